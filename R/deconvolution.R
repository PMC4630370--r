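# Target-profile deconvolution for AP-MS hit lists: subtraction of matrix
# binders and central-proteome proteins, CRAPome annotation, complex overlap.

#' Normalise a protein accession
#'
#' Strips isoform suffixes (`P12814-2`) and sequence versions (`P12814.3`)
#' so matching across lists happens at the root-accession level.
#'
#' @param x Character vector of accessions.
#' @return Character vector of root accessions.
#' @export
normalize_accession <- function(x) {
  sub("[.-][0-9]+$", "", x)
}

new_target_profile <- function(accessions, n_identified, removed_sticky,
                               central_flagged = character(),
                               crapome = NULL) {
  structure(
    list(accessions = accessions,
         n_identified = n_identified,
         removed_sticky = removed_sticky,
         central_flagged = central_flagged,
         crapome = crapome),
    class = "target_profile"
  )
}

#' @export
print.target_profile <- function(x, ...) {
  cat("Target profile:", length(x$accessions), "accessions\n")
  cat("  identified:", x$n_identified,
      " sticky removed:", length(x$removed_sticky),
      " central removed:", length(x$central_flagged), "\n")
  invisible(x)
}

#' Remove nonspecific (matrix-binding) proteins
#'
#' Proteins also retained on the unloaded affinity matrix are sticky,
#' nonspecific binders and are ruled out of the target profile.
#'
#' @param identified Character vector of identified accessions.
#' @param sticky Character vector of control pull-down (nonspecific)
#'   accessions.
#' @return A `target_profile` with the surviving accessions (order-stable)
#'   and the removed set recorded.
#' @export
subtract_nonspecific <- function(identified, sticky) {
  identified <- normalize_accession(unique(identified))
  sticky <- normalize_accession(unique(sticky))
  removed <- intersect(identified, sticky)
  new_target_profile(
    accessions = identified[!(identified %in% sticky)],
    n_identified = length(identified),
    removed_sticky = removed
  )
}

#' Subtract central-proteome proteins from a target profile
#'
#' Members of the ubiquitously expressed "central proteome" are treated as
#' abundant background and removed; the removed set is flagged in the
#' profile for reporting.
#'
#' @param profile A `target_profile` (or character vector of accessions).
#' @param central Character vector of central-proteome accessions.
#' @return Updated `target_profile`.
#' @export
subtract_central_proteome <- function(profile, central) {
  if (is.character(profile)) profile <- subtract_nonspecific(profile, character())
  stopifnot(inherits(profile, "target_profile"))
  central <- normalize_accession(unique(central))
  flagged <- profile$accessions[profile$accessions %in% central]
  profile$central_flagged <- flagged
  profile$accessions <- profile$accessions[!(profile$accessions %in% central)]
  profile
}

#' Annotate a profile with CRAPome average spectral counts
#'
#' Each accession touched by the deconvolution (current members plus the
#' central-flagged ones) is annotated with its average spectral count in
#' AP-MS contaminant repositories, a measure of how commonly it appears as
#' background. Annotation only: no member is removed unless
#' `filter = TRUE`.
#'
#' @param profile A `target_profile`.
#' @param counts Named numeric vector, accession -> average spectral count.
#' @param threshold Count above which (strictly) a protein is reported as a
#'   frequent contaminant (default 2).
#' @param filter If `TRUE`, additionally remove current members whose count
#'   exceeds the threshold (default `FALSE`).
#' @return Updated `target_profile`; the annotation table is in
#'   `$crapome` (columns `accession`, `count`, `above_threshold`) and the
#'   number of annotated accessions above the threshold in
#'   `$n_crapome_above`.
#' @export
crapome_annotate <- function(profile, counts, threshold = 2, filter = FALSE) {
  stopifnot(inherits(profile, "target_profile"), threshold >= 0)
  if (length(counts) && any(counts < 0)) {
    stop("CRAPome spectral counts must be non-negative", call. = FALSE)
  }
  if (length(counts)) names(counts) <- normalize_accession(names(counts))
  scope <- unique(c(profile$accessions, profile$central_flagged))
  cnt <- unname(counts[match(scope, names(counts))])
  ann <- data.frame(accession = scope, count = cnt,
                    above_threshold = !is.na(cnt) & cnt > threshold,
                    stringsAsFactors = FALSE)
  profile$crapome <- ann
  profile$n_crapome_above <- sum(ann$above_threshold)
  if (filter) {
    drop <- ann$accession[ann$above_threshold]
    profile$accessions <- profile$accessions[!(profile$accessions %in% drop)]
  }
  profile
}

#' Protein complexes overlapping a target profile
#'
#' @param profile A `target_profile` or character vector of accessions.
#' @param catalog Named list: complex id -> character vector of member
#'   accessions.
#' @param min_members Minimum number of complex members that must be present
#'   in the profile (default 2).
#' @return Data frame (`complex_id`, `n_present`, `complex_size`,
#'   `members_present`) sorted by members present (descending), ties by
#'   complex id.
#' @export
complex_overlap <- function(profile, catalog, min_members = 2L) {
  stopifnot(min_members >= 1)
  acc <- if (inherits(profile, "target_profile")) profile$accessions else profile
  acc <- normalize_accession(acc)
  hits <- lapply(names(catalog), function(id) {
    members <- normalize_accession(catalog[[id]])
    present <- intersect(members, acc)
    if (length(present) >= min_members) {
      data.frame(complex_id = id, n_present = length(present),
                 complex_size = length(unique(members)),
                 members_present = paste(sort(present), collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(complex_id = character(), n_present = integer(),
                      complex_size = integer(), members_present = character(),
                      stringsAsFactors = FALSE))
  }
  hits[order(-hits$n_present, hits$complex_id), , drop = FALSE]
}

#' Full target-deconvolution chain
#'
#' Runs, in order: (1) subtraction of nonspecific matrix binders,
#' (2) subtraction of central-proteome proteins, (3) CRAPome spectral-count
#' annotation, then (4) protein-complex overlap, and assembles a count
#' report.
#'
#' @param identified Accessions identified in the drug pull-down, or a
#'   `pulldown_fixture` from [gen_pulldown_fixture()] (in which case
#'   `sticky`/`central`/`crapome_counts` are taken from the fixture).
#' @param sticky Control pull-down accessions.
#' @param central Central-proteome accessions.
#' @param crapome_counts Named numeric vector of average spectral counts
#'   (optional).
#' @param complexes Named list complex id -> members (optional).
#' @param crapome_threshold Strict lower bound for the contaminant count
#'   report (default 2).
#' @param min_members Minimum complex members present (default 2).
#' @param crapome_filter Remove members above the CRAPome threshold
#'   (default `FALSE`, annotation only).
#' @return List with `profile` (a `target_profile`), `report` (named counts:
#'   `n_identified`, `n_sticky`, `n_profile`, `n_central`, `n_filtered`,
#'   `n_crapome_above`), and `complex_hits`.
#' @examples
#' fx <- gen_pulldown_fixture(20, 5, 4, seed = 1)
#' deconvolve(fx)$report
#' @export
deconvolve <- function(identified, sticky = NULL, central = NULL,
                       crapome_counts = NULL, complexes = NULL,
                       crapome_threshold = 2, min_members = 2L,
                       crapome_filter = FALSE) {
  if (inherits(identified, "pulldown_fixture")) {
    fx <- identified
    identified <- fx$identified
    if (is.null(sticky)) sticky <- fx$sticky
    if (is.null(central)) central <- fx$central
    if (is.null(crapome_counts)) crapome_counts <- fx$crapome_counts
  }
  if (is.null(sticky)) sticky <- character()
  if (is.null(central)) central <- character()
  profile <- subtract_nonspecific(identified, sticky)
  n_profile <- length(profile$accessions)
  profile <- subtract_central_proteome(profile, central)
  profile <- crapome_annotate(profile, crapome_counts %||% numeric(),
                              threshold = crapome_threshold,
                              filter = crapome_filter)
  hits <- if (!is.null(complexes)) {
    complex_overlap(profile, complexes, min_members = min_members)
  }
  report <- list(
    n_identified = profile$n_identified,
    n_sticky = length(profile$removed_sticky),
    n_profile = n_profile,
    n_central = length(profile$central_flagged),
    n_filtered = length(profile$accessions),
    n_crapome_above = profile$n_crapome_above
  )
  list(profile = profile, report = report, complex_hits = hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
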