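#' Read wide-format SMART trial data from CSV
#'
#' One row per completed patient; required columns `A1`, `O2`, `A2`, `Y`
#' (exact names), optional `O1`.  Any other columns (e.g. `ID`, `group`) are
#' dropped with a notice — the functions identify treatment sequences from
#' the `A` and `O` values alone.  Data whose variables are named differently
#' must be renamed before reading.
#'
#' @param path path to a CSV file.
#' @param family outcome family used for validation.
#' @return A data frame with columns `O1` (if present), `A1`, `O2`, `A2`, `Y`.
#' @export
read_trial_csv <- function(path, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  raw <- utils::read.csv(path)
  if (nrow(raw) == 0L) stop("no records in '", path, "'")
  required <- c("A1", "O2", "A2", "Y")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "),
         " (rename the variables to {O1, A1, O2, A2, Y})")
  keep <- intersect(c("O1", required), names(raw))
  extra <- setdiff(names(raw), keep)
  if (length(extra))
    message("ignoring column(s) not used by the analysis: ",
            paste(extra, collapse = ", "))
  validate_trial(raw[keep], family)
}

#' Read a sequence information matrix from CSV
#'
#' Expects the exact header `SEQ,A1,PI1,O2,P2,A2,PI2,MEAN,SD` and validates
#' the design it describes.
#'
#' @param path path to a CSV file.
#' @return The validated SIM data frame (the `"smart_design"` is available
#'   via [smart_design()]).
#' @export
read_sim_csv <- function(path) {
  raw <- utils::read.csv(path)
  smart_design(raw)$sim
}
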