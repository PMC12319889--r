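# Minimal GIFTI (.gii) I/O: ASCII-encoded POINTSET/TRIANGLE/LABEL data arrays,
# which is all the surface plumbing here needs. Binary/Base64 encodings and
# CIFTI are intentionally not handled.

gii_type_map <- c(NIFTI_TYPE_FLOAT32 = "double", NIFTI_TYPE_FLOAT64 = "double",
                  NIFTI_TYPE_INT32 = "integer", NIFTI_TYPE_UINT8 = "integer")

read_gifti_arrays <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(das) == 0L) stop("no DataArray elements in ", path)
  out <- lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("only ASCII-encoded GIFTI is supported, got encoding: ", enc)
    dtype <- xml2::xml_attr(da, "DataType")
    ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(i)
      as.integer(xml2::xml_attr(da, paste0("Dim", i))), integer(1))
    txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    vals <- scan(text = txt, what = numeric(), quiet = TRUE)
    if (length(vals) != prod(dims))
      stop("DataArray length ", length(vals), " does not match dims ",
           paste(dims, collapse = "x"))
    storage <- gii_type_map[[dtype]]
    if (identical(storage, "integer")) vals <- as.integer(round(vals))
    # GIFTI arrays are row-major; R arrays are column-major
    arr <- if (ndim == 2L) matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
           else vals
    list(intent = xml2::xml_attr(da, "Intent"), data = arr)
  })
  # label table, if present
  lt <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  labels <- NULL
  if (length(lt) > 0L) {
    labels <- stats::setNames(xml2::xml_text(lt),
                              xml2::xml_attr(lt, "Key"))
  }
  attr(out, "label_table") <- labels
  out
}

gii_format_array <- function(x, digits = 17) {
  if (is.matrix(x)) {
    paste(apply(x, 1L, function(r)
      paste(format(r, digits = digits, scientific = FALSE, trim = TRUE),
            collapse = " ")), collapse = "\n")
  } else {
    paste(format(x, digits = digits, scientific = FALSE, trim = TRUE),
          collapse = "\n")
  }
}

gii_data_array_xml <- function(x, intent, dtype) {
  dims <- if (is.matrix(x)) dim(x) else length(x)
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'),
    intent, dtype, length(dims), dim_attrs, gii_format_array(x))
}

write_gifti <- function(path, arrays, label_table = NULL) {
  body <- vapply(arrays, function(a)
    gii_data_array_xml(a$data, a$intent, a$dtype), character(1))
  lt <- ""
  if (!is.null(label_table)) {
    lt <- paste0("<LabelTable>\n",
                 paste(sprintf('<Label Key="%s">%s</Label>',
                               names(label_table), label_table),
                       collapse = "\n"),
                 "\n</LabelTable>\n")
  }
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="', length(arrays),
                '">\n', lt, paste(body, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

write_gifti_surface <- function(vertices, triangles, path) {
  write_gifti(path, list(
    list(data = vertices, intent = "NIFTI_INTENT_POINTSET",
         dtype = "NIFTI_TYPE_FLOAT32"),
    list(data = triangles - 1L, intent = "NIFTI_INTENT_TRIANGLE",
         dtype = "NIFTI_TYPE_INT32")))
}

write_gifti_labels <- function(codes, label_table, path) {
  write_gifti(path, list(
    list(data = as.integer(codes), intent = "NIFTI_INTENT_LABEL",
         dtype = "NIFTI_TYPE_INT32")),
    label_table = label_table)
}

write_gifti_metric <- function(values, path) {
  write_gifti(path, list(
    list(data = as.numeric(values), intent = "NIFTI_INTENT_NONE",
         dtype = "NIFTI_TYPE_FLOAT32")))
}
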