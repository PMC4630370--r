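# End-to-end orchestration: the chemical-proteomics arm (deconvolution ->
# affinity -> enrichment -> subnetwork ranking) and the expression arm
# (reporter fitting -> GOF filter -> aggregation -> normalisation ->
# thresholds -> calls -> trends), plus the intersection of both profiles.

write_manifest <- function(out_dir, params) {
  man <- data.frame(key = c("package", "version", names(params)),
                    value = c("targdecon",
                              as.character(utils::packageVersion("targdecon")),
                              vapply(params, function(p) paste(format(p), collapse = ","),
                                     character(1))),
                    stringsAsFactors = FALSE)
  write_tsv(man, file.path(out_dir, "manifest.tsv"))
}

#' Run the chemical-proteomics arm
#'
#' Deconvolves the pull-down hit list (sticky subtraction, central-proteome
#' subtraction, CRAPome annotation, complex overlap), derives
#' emPAI-proportional affinity scores for the filtered targets, tests the
#' filtered profile for term enrichment against the identified background,
#' and ranks functional subnetworks by perturbation score when an
#' interactome is supplied.
#'
#' @param pulldown A `pulldown_fixture` (see [gen_pulldown_fixture()]) or a
#'   list with the same fields (`identified`, `sticky`, `central`,
#'   `crapome_counts`, `observed_peptides`, `sequences`).
#' @param complexes Named list complex id -> members (optional).
#' @param annotations Named list term -> accessions for enrichment
#'   (optional).
#' @param network Interactome for subnetwork scoring: a `network_fixture`
#'   or a list with `graph` (igraph) and `term2nodes` (optional).
#' @param network_affinities Affinity map to use for subnetwork scoring;
#'   defaults to the emPAI-derived affinities of the filtered profile.
#' @param crapome_threshold,min_members,alpha,mass_window,max_missed
#'   Stage parameters (defaults 2, 2, 0.05, c(798, 5997) Da, 0).
#' @param forced_full_affinity Accessions pinned to affinity 1 (e.g. a
#'   validated target absent from the pull-down).
#' @param out_dir Optional directory: writes profile, report, affinity,
#'   enrichment and subnetwork tables plus a run manifest.
#' @return List with `report`, `profile`, `complex_hits`, `empai`,
#'   `affinities`, `enrichment`, `subnetworks`.
#' @export
run_chemical <- function(pulldown, complexes = NULL, annotations = NULL,
                         network = NULL, network_affinities = NULL,
                         crapome_threshold = 2, min_members = 2L,
                         alpha = 0.05, mass_window = c(798, 5997),
                         max_missed = 0L, forced_full_affinity = character(),
                         out_dir = NULL) {
  dec <- deconvolve(pulldown$identified, pulldown$sticky, pulldown$central,
                    pulldown$crapome_counts, complexes = complexes,
                    crapome_threshold = crapome_threshold,
                    min_members = min_members)
  profile <- dec$profile

  empai_tab <- NULL; affinities <- NULL
  if (!is.null(pulldown$sequences)) {
    acc <- intersect(profile$accessions, names(pulldown$sequences))
    rows <- lapply(acc, function(a) {
      n_obs <- pulldown$observed_peptides[[a]] %||% 1L
      cbind(accession = a,
            protein_empai(pulldown$sequences[[a]], n_obs,
                          mass_min = mass_window[1], mass_max = mass_window[2],
                          max_missed = max_missed))
    })
    empai_tab <- do.call(rbind, rows)
    ok <- !is.na(empai_tab$empai) & empai_tab$empai > 0
    if (any(ok) || length(forced_full_affinity)) {
      affinities <- affinity_from_empai(
        stats::setNames(empai_tab$empai[ok], empai_tab$accession[ok]),
        forced_full_affinity)
      empai_tab$affinity <- unname(affinities[empai_tab$accession])
    }
  }

  enr <- NULL
  if (!is.null(annotations)) {
    enr <- enrich_terms(profile$accessions, normalize_accession(pulldown$identified),
                        annotations, alpha = alpha)
  }

  subnets <- NULL
  if (!is.null(network)) {
    aff <- network_affinities %||% affinities
    if (is.null(aff)) stop("subnetwork scoring needs an affinity map", call. = FALSE)
    sn <- extract_subnetworks(network$graph, network$term2nodes)
    subnets <- rank_perturbed(sn, aff, network$graph)
  }

  res <- list(report = dec$report, profile = profile,
              complex_hits = dec$complex_hits, empai = empai_tab,
              affinities = affinities, enrichment = enr, subnetworks = subnets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(accession = profile$accessions), file.path(out_dir, "profile.tsv"))
    write_tsv(as.data.frame(dec$report), file.path(out_dir, "report.tsv"))
    if (!is.null(empai_tab)) write_tsv(empai_tab, file.path(out_dir, "empai.tsv"))
    if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(subnets)) write_tsv(subnets, file.path(out_dir, "subnetworks.tsv"))
    write_manifest(out_dir, list(crapome_threshold = crapome_threshold,
                                 min_members = min_members, alpha = alpha,
                                 mass_window = mass_window,
                                 max_missed = max_missed))
  }
  res
}

#' Run the expression-proteomics arm
#'
#' Fits reporter-ion ratios for every spectrum, applies the GOF filter,
#' aggregates peptides to proteins, normalises per time point, derives
#' median/SD significance thresholds (or replays supplied ones), calls
#' differential expression including ON/OFF, groups temporal trends, and
#' optionally tests the significant set for term enrichment.
#'
#' @param experiment An `itraq_experiment` (see [gen_itraq_experiment()])
#'   or a list with `spectra` (named list of `isotope_pattern`s),
#'   `peptide_map` (peptide -> protein) and `templates`.
#' @param min_gof GOF cutoff (default 0.8).
#' @param p_level Two-sided significance level for the thresholds
#'   (default 0.1).
#' @param thresholds Optional per-time-point fold-change thresholds to
#'   replay (e.g. `c(2.6, 2.6, 2.4)`); when `NULL` they are computed from
#'   the normalised population.
#' @param annotations Named list term -> accessions (optional).
#' @param alpha Enrichment significance level (default 0.05).
#' @param out_dir Optional output directory (quant table, thresholds,
#'   trends, enrichment, manifest).
#' @return List with `quant` (calls included), `thresholds`, `trends`,
#'   `enrichment`, `n_spectra`, `n_retained`.
#' @export
run_expression <- function(experiment, min_gof = 0.8, p_level = 0.1,
                           thresholds = NULL, annotations = NULL,
                           alpha = 0.05, out_dir = NULL) {
  spectra <- experiment$spectra
  fits <- lapply(spectra, fit_reporter_ratios, templates = experiment$templates)
  pt <- peptide_ratio_table(fits, names(spectra))
  quant <- protein_quant(pt, experiment$peptide_map, min_gof = min_gof)
  quant <- normalize_ratios(quant)
  quant <- add_signed_fc(quant)
  if (is.null(thresholds)) {
    lg <- log2(as.matrix(quant[, ratio_cols()]))
    colnames(lg) <- TIMEPOINTS
    thresholds <- compute_thresholds(lg, p_level = p_level)
  }
  quant <- call_differential(quant, thresholds)
  trends <- cluster_trends(quant)
  enr <- NULL
  if (!is.null(annotations)) {
    sig <- quant$accession[rowSums(as.matrix(quant[, sig_cols()])) > 0]
    enr <- enrich_terms(sig, quant$accession, annotations, alpha = alpha)
  }
  res <- list(quant = quant, thresholds = thresholds, trends = trends,
              enrichment = enr, n_spectra = length(spectra),
              n_retained = sum(pt$gof >= min_gof))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(quant, file.path(out_dir, "quant.tsv"))
    thr <- if (inherits(thresholds, "de_thresholds")) thresholds
           else data.frame(time = TIMEPOINTS, tau = thresholds)
    write_tsv(thr, file.path(out_dir, "thresholds.tsv"))
    write_tsv(trends, file.path(out_dir, "trends.tsv"))
    if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    write_manifest(out_dir, list(min_gof = min_gof, p_level = p_level))
  }
  res
}

#' Intersect the chemical and expression profiles
#'
#' Reports (a) the accession intersection of the target profile and the
#' differentially expressed set, (b) interactome edges connecting a target
#' to a differential protein, and (c) a node-attribute table for external
#' visualisation.
#'
#' @param chemical Target profile (`target_profile` or character vector).
#' @param de_proteins Character vector of differentially expressed
#'   accessions.
#' @param graph Optional interactome ([igraph::graph]).
#' @return List with `shared`, `pairs` (data frame), `node_attributes`.
#' @export
intersect_profiles <- function(chemical, de_proteins, graph = NULL) {
  chem <- if (inherits(chemical, "target_profile")) chemical$accessions else chemical
  chem <- normalize_accession(chem)
  de <- normalize_accession(de_proteins)
  shared <- intersect(chem, de)
  pairs <- if (!is.null(graph)) interaction_overlap(chem, de, graph)
           else data.frame(target = character(), de_protein = character())
  all_acc <- sort(union(chem, de))
  attrs <- data.frame(accession = all_acc,
                      in_chemical = all_acc %in% chem,
                      in_differential = all_acc %in% de,
                      stringsAsFactors = FALSE)
  list(shared = sort(shared), pairs = pairs, node_attributes = attrs)
}
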