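#' Generator configuration for a virtual study
#'
#' Bundles everything that determines a synthetic dataset: seed, trial
#' design, generative structural parameters, IIV and residual
#' specifications, and the molecular-weight constants. The same
#' configuration always produces byte-identical output.
#'
#' @param seed integer seed.
#' @param design a [trial_design()].
#' @param tmdd a [tmdd_params()] object.
#' @param dr a [dr_pair()] object.
#' @param iiv list with `pk`, `tem`, `treg` [iiv_spec()] entries; set all
#'   CVs to zero (with `zero_noise = TRUE`) for a deterministic dataset.
#' @param residual a [residual_spec()].
#' @param mw_mab_kda,mw_sr_kda molecular weights (kDa).
#' @param zero_noise convenience flag: replaces `iiv` and `residual` with
#'   zero-variance versions so the dataset equals the model predictions.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             design = trial_design(),
                             tmdd = tmdd_params(),
                             dr = dr_pair(),
                             iiv = list(pk = iiv_pk_default(),
                                        tem = iiv_tem_default(),
                                        treg = iiv_treg_default()),
                             residual = residual_spec(),
                             mw_mab_kda = MW_MAB_KDA,
                             mw_sr_kda = MW_SR_KDA,
                             zero_noise = FALSE) {
  if (zero_noise) {
    zero_cv <- function(s) iiv_spec(setNames(rep(0, length(s$cv)),
                                             names(s$cv)))
    iiv <- lapply(iiv, zero_cv)
    residual <- residual_spec(PK = list(prop = 0), SIL7R = list(prop = 0),
                              FREERO = list(add = 0), TEM = list(prop = 0),
                              TREG = list(prop = 0))
  }
  structure(list(seed = as.integer(seed), design = design, tmdd = tmdd,
                 dr = dr, iiv = iiv, residual = residual,
                 mw_mab_kda = mw_mab_kda, mw_sr_kda = mw_sr_kda),
            class = "generator_config")
}

#' Generate a complete virtual study
#'
#' Runs [simulate_trial()] under a [generator_config()] and returns both
#' the long-format dataset and a "truth sidecar" with every subject's
#' generative individual parameters, for parameter-recovery testing.
#'
#' @param config a [generator_config()].
#' @param streams passed to [simulate_trial()]; `"tcell"` skips the
#'   ODE-based streams.
#' @return List with elements `data` (the dataset) and `truth` (per-subject
#'   generative parameters).
#' @export
generate_study <- function(config = generator_config(),
                           streams = c("all", "tcell", "tmdd")) {
  stopifnot(inherits(config, "generator_config"))
  streams <- match.arg(streams)
  data <- simulate_trial(design = config$design, tmdd = config$tmdd,
                         dr = config$dr, iiv = config$iiv,
                         residual = config$residual, seed = config$seed,
                         streams = streams,
                         mw_mab_kda = config$mw_mab_kda,
                         mw_sr_kda = config$mw_sr_kda)
  truth <- attr(data, "truth")
  attr(data, "truth") <- NULL
  list(data = data, truth = truth)
}

.DATASET_COLUMNS <- c("ID", "ARM", "TIME", "EVID", "MDV", "AMT", "DOSE",
                      "DOSE2WK", "WT", "STREAM", "DV", "PRED", "BLQ")
.STREAM_LEVELS <- c(".", "PK", "SIL7R", "FREERO", "TEM", "TREG")

#' Read and write NONMEM-style datasets
#'
#' The on-disk dialect is a plain CSV with columns `ID, ARM, TIME, EVID,
#' MDV, AMT, DOSE, DOSE2WK, WT, STREAM, DV, PRED, BLQ`; dose rows carry
#' `EVID = 1` and an `AMT` in mg with missing `DV`, observation rows carry
#' `EVID = 0` and one of the five stream labels (`PK`, `SIL7R`, `FREERO`,
#' `TEM`, `TREG`; `.` on dose rows). Column order in the file is not
#' significant. A write/read round trip is lossless to numeric precision.
#'
#' @param dataset a dataset `data.frame`.
#' @param path file path.
#' @return `read_dataset()`: the dataset; `write_dataset()`: the path,
#'   invisibly.
#' @export
write_dataset <- function(dataset, path) {
  miss <- setdiff(.DATASET_COLUMNS, names(dataset))
  if (length(miss)) stop("dataset lacks column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(dataset[, .DATASET_COLUMNS], path, row.names = FALSE,
            quote = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = ".")
  miss <- setdiff(setdiff(.DATASET_COLUMNS, "STREAM"), names(d))
  if (length(miss)) stop("malformed dataset ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  if (!"STREAM" %in% names(d)) d$STREAM <- "."
  d$STREAM[is.na(d$STREAM)] <- "."
  bad <- which(!d$STREAM %in% .STREAM_LEVELS)
  if (length(bad)) {
    stop("malformed dataset ", path, ": unknown stream label '",
         d$STREAM[bad[1]], "' at data line ", bad[1])
  }
  bad <- which(d$EVID == 0 & is.na(d$DV))
  if (length(bad)) {
    stop("malformed dataset ", path, ": observation row without DV at ",
         "data line ", bad[1])
  }
  d[, .DATASET_COLUMNS]
}

#' Write the truth sidecar of a generated study
#'
#' @param truth the `truth` element of [generate_study()].
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, dataframe = "columns")
  invisible(path)
}
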