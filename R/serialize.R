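# Single-archive model format: an eight-byte magic string, a four-byte
# little-endian header length, a UTF-8 JSON header (package version,
# model class, key configuration), then the binary payload holding every
# tensor.  Round-trips are bit-exact.

model_magic <- charToRaw("MYXOMDL1")

model_header <- function(object) {
  h <- list(package = "myxoclass",
            version = as.character(utils::packageVersion("myxoclass")),
            r_version = paste(R.version$major, R.version$minor, sep = "."),
            class = class(object))
  if (inherits(object, "myxo_cnn")) {
    h$table3_config <- object$config$table3_config
    h$n_classes <- length(object$classes)
    h$seed <- object$config$training$seed
  }
  if (inherits(object, "ecnn")) {
    h$head <- object$head_spec$kind
    h$seed <- object$head_spec$seed
  }
  if (inherits(object, "elm")) {
    h$n_hidden <- object$n_hidden
  }
  h
}

#' Write a model archive
#'
#' Serialises a fitted model (`myxo_cnn`, `ecnn` or any ELM-family model)
#' to a single archive file with a JSON header and a binary tensor
#' payload.  [read_model()] restores it bit-exactly.
#'
#' @param object the fitted model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  header <- jsonlite::toJSON(model_header(object), auto_unbox = TRUE)
  hraw <- charToRaw(as.character(header))
  payload <- serialize(object, NULL, xdr = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(model_magic, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(payload, con)
  invisible(path)
}

#' Read a model archive
#'
#' @param path archive written by [write_model()].
#' @param header_only return just the parsed JSON header.
#' @return The restored model object (or the header list).
#' @export
read_model <- function(path, header_only = FALSE) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(model_magic))
  if (!identical(magic, model_magic)) {
    stop("'", path, "' is not a model archive (bad magic)")
  }
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (header_only) return(header)
  sz <- file.info(path)$size
  payload <- readBin(con, "raw", sz)
  unserialize(payload)
}
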