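#' Serialize a fitted parameter set to a structured text file
#'
#' Writes an [an_params()] or [tmoss_params()] object as a key/value
#' (Debian-control-style) text record, including the configuration metadata
#' needed to re-evaluate the surface unambiguously: coefficient grouping,
#' log base, species label and package version. Optional standard
#' deviations are stored under `sd_<name>` keys so bootstrap runs can be
#' reproduced from the file alone.
#'
#' @param params An `"an_params"` or `"tmoss_params"` object.
#' @param path Output file path.
#' @param sds Optional named numeric vector of per-coefficient SDs.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, sds = NULL) {
  if (inherits(params, "an_params")) {
    type <- "an_params"
    keys <- c("a", "b", "c", "d", "e", "f", "g", "h", "i", "AQE")
    meta <- c(grouping = params$grouping, log_base = params$log_base,
              species = params$species)
  } else if (inherits(params, "tmoss_params")) {
    type <- "tmoss_params"
    keys <- c("j", "k", "l", "m")
    meta <- c(log_base = params$log_base)
  } else {
    stop("write_params handles an_params and tmoss_params objects")
  }
  rec <- c(type = type,
           stats::setNames(vapply(params[keys], format, "", digits = 17),
                           keys),
           meta,
           version = as.character(utils::packageVersion("sphagnumflux")))
  if (!is.null(sds))
    rec <- c(rec, stats::setNames(vapply(sds, format, "", digits = 17),
                                  paste0("sd_", names(sds))))
  write.dcf(t(as.matrix(rec)), path)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#'
#' @param path File path.
#' @return The reconstructed parameter object; any stored SDs are attached
#'   as attribute `"sds"`.
#' @export
read_params <- function(path) {
  rec <- read.dcf(path)[1, ]
  type <- rec[["type"]]
  num <- function(k) as.numeric(rec[[k]])
  out <- if (identical(type, "an_params")) {
    an_params(a = num("a"), b = num("b"), c = num("c"), d = num("d"),
              e = num("e"), f = num("f"), g = num("g"), h = num("h"),
              i = num("i"), AQE = num("AQE"),
              grouping = rec[["grouping"]], log_base = rec[["log_base"]],
              species = if ("species" %in% names(rec)) rec[["species"]]
                        else NA_character_)
  } else if (identical(type, "tmoss_params")) {
    tmoss_params(j = num("j"), k = num("k"), l = num("l"), m = num("m"),
                 log_base = rec[["log_base"]])
  } else {
    stop("unrecognised parameter file type: ", type)
  }
  sd_keys <- grep("^sd_", names(rec), value = TRUE)
  if (length(sd_keys) > 0)
    attr(out, "sds") <- stats::setNames(as.numeric(rec[sd_keys]),
                                        sub("^sd_", "", sd_keys))
  out
}
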