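# Packaged reference tables for the CIGB-552 study: the 55 filtered
# chemical-proteomics targets, the 10 perturbed functional subnetworks,
# and the 72 differentially expressed proteins of the HT-29 time course.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "targdecon")
  if (!nzchar(p)) stop("fixture file not found: ", file, call. = FALSE)
  p
}

read_fixture <- function(file, n_expected, cols) {
  tab <- tryCatch(
    utils::read.delim(fixture_path(file), stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("malformed fixture file ", file, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) != n_expected || !all(cols %in% names(tab))) {
    stop("malformed fixture file ", file, ": expected ", n_expected,
         " rows with columns ", paste(cols, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Published CIGB-552 reference tables
#'
#' Loads the three reference tables packaged with targdecon, transcribed
#' from the published CIGB-552 proteomic study:
#' * `targets` - the 55 filtered chemical-proteomics targets with MASCOT
#'   score and emPAI (reference data: the underlying observed/observable
#'   peptide counts are not published, so these emPAI values are fixtures,
#'   not recomputation targets);
#' * `subnetworks` - the 10 perturbed functional subnetworks with node and
#'   target counts and the published S_net scores (reference data: the
#'   study's interactome and annotation snapshots are not available);
#' * `differential` - the 72 differentially expressed proteins of the
#'   treated HT-29 time course, with signed fold changes or ON/OFF status
#'   at 40 min / 2 h / 5 h, the published per-cell significance calls, and
#'   a flag for the 8 proteins also found by chemical proteomics.
#'
#' The per-time-point fold-change thresholds of the differential table are
#' in `attr(x$differential, "thresholds")` (2.6, 2.6, 2.4).
#'
#' @return List with data frames `targets` (55 rows), `subnetworks`
#'   (10 rows), `differential` (72 rows).
#' @export
cigb552_tables <- function() {
  targets <- read_fixture("cigb552_targets.tsv", 55,
                          c("accession", "gene", "score", "empai"))
  targets$score <- as.numeric(targets$score)
  targets$empai <- as.numeric(targets$empai)

  subnet <- read_fixture("cigb552_subnetworks.tsv", 10,
                         c("subnetwork", "go_id", "nodes", "targets", "s_net"))
  for (cl in c("nodes", "targets", "s_net")) subnet[[cl]] <- as.numeric(subnet[[cl]])

  diff <- read_fixture("cigb552_differential.tsv", 72,
                       c("accession", "gene", "score",
                         paste0("fc_", TIMEPOINTS), paste0("sig_", TIMEPOINTS),
                         "chem_overlap"))
  diff$score <- as.numeric(diff$score)
  for (tp in TIMEPOINTS) {
    raw <- diff[[paste0("fc_", tp)]]
    diff[[paste0("status_", tp)]] <- ifelse(raw %in% c("ON", "OFF"), raw, "normal")
    diff[[paste0("fc_", tp)]] <- suppressWarnings(as.numeric(raw))
    diff[[paste0("sig_", tp)]] <- as.logical(diff[[paste0("sig_", tp)]])
  }
  diff$chem_overlap <- as.logical(diff$chem_overlap)
  attr(diff, "thresholds") <- c(`40min` = 2.6, `2h` = 2.6, `5h` = 2.4)
  list(targets = targets, subnetworks = subnet, differential = diff)
}
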