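# Synthetic-data generators: every input the pipeline consumes can be
# produced with known ground truth, deterministically under a seed.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

syn_accessions <- function(n, prefix = "SYN") {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

random_protein_sequence <- function(len) {
  paste(sample(names(residue_masses), len, replace = TRUE), collapse = "")
}

#' Generate a pull-down fixture for target deconvolution
#'
#' Emulates an AP-MS pull-down inventory: identified accessions, the subset
#' also retained on the unloaded matrix (sticky), the subset of non-sticky
#' accessions belonging to the central proteome, CRAPome-style average
#' spectral counts (high for central/sticky proteins), observed-peptide
#' counts and random protein sequences. Deterministic under `seed`.
#'
#' @param n_total Number of identified proteins.
#' @param n_sticky Number flagged as nonspecific matrix binders.
#' @param n_central_in_profile Number of non-sticky proteins flagged as
#'   central-proteome members.
#' @param seed RNG seed.
#' @return A `pulldown_fixture`: list with `identified`, `sticky`,
#'   `central`, `crapome_counts`, `observed_peptides`, `sequences`, `seed`.
#' @examples
#' fx <- gen_pulldown_fixture(265, 104, 106, seed = 1)
#' deconvolve(fx)$report[c("n_profile", "n_filtered")]  # 161, 55
#' @export
gen_pulldown_fixture <- function(n_total, n_sticky, n_central_in_profile, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_sticky + n_central_in_profile > n_total) {
    stop("n_sticky + n_central_in_profile must not exceed n_total", call. = FALSE)
  }
  local_seed(seed, {
    acc <- syn_accessions(n_total)
    sticky <- sort(sample(acc, n_sticky))
    central <- sort(sample(setdiff(acc, sticky), n_central_in_profile))
    sequences <- vapply(acc, function(a) random_protein_sequence(sample(60:200, 1)),
                        character(1))
    observed <- stats::setNames(stats::rpois(n_total, 4) + 1L, acc)
    # contaminant-prone proteins (central, sticky) carry high average
    # spectral counts; a minority of the remainder carries low counts
    cnt <- c(
      stats::setNames(stats::rlnorm(length(central), meanlog = 1.8, sdlog = 1), central),
      stats::setNames(stats::rlnorm(length(sticky), meanlog = 1.2, sdlog = 1), sticky)
    )
    others <- setdiff(acc, c(central, sticky))
    some <- sample(others, round(0.2 * length(others)))
    cnt <- c(cnt, stats::setNames(stats::rlnorm(length(some), meanlog = -0.5, sdlog = 0.7), some))
    structure(
      list(identified = acc, sticky = sticky, central = central,
           crapome_counts = cnt, observed_peptides = observed,
           sequences = sequences, seed = seed),
      class = "pulldown_fixture"
    )
  })
}

#' Generate a synthetic reporter-region spectrum
#'
#' The spectrum is the linear combination of the channel templates weighted
#' by `ratios`, optionally perturbed by multiplicative Gaussian noise of
#' relative magnitude `noise_frac` and clipped at zero.
#'
#' @param ratios Non-negative channel amplitudes (one per template; channel
#'   114 first).
#' @param templates Channel templates from [reporter_templates()] on a
#'   common grid.
#' @param noise_frac Relative noise magnitude (default 0, exact mixture).
#' @param seed Optional RNG seed for the noise draw.
#' @return An `isotope_pattern` (not normalised: intensities are on the
#'   amplitude scale of `ratios`).
#' @export
gen_reporter_spectrum <- function(ratios, templates, noise_frac = 0, seed = NULL) {
  if (any(ratios < 0)) stop("channel ratios must be non-negative", call. = FALSE)
  stopifnot(length(ratios) == length(templates), noise_frac >= 0)
  grid <- templates[[1]]$grid
  y <- numeric(length(grid))
  for (i in seq_along(templates)) {
    y <- y + ratios[i] * as_intensity(templates[[i]], grid)
  }
  if (noise_frac > 0) {
    noisify <- function() pmax(0, y * (1 + stats::rnorm(length(y), 0, noise_frac)))
    y <- if (is.null(seed)) noisify() else local_seed(seed, noisify())
  }
  new_isotope_pattern(grid = grid, intensity = y)
}

#' Generate a synthetic 4-plex iTRAQ time-course experiment
#'
#' Plants ground truth at the protein level and emits one reporter-region
#' spectrum per peptide. A fraction of proteins is regulated (true ratio
#' `effect_fc` or `1/effect_fc` at a random non-empty subset of the three
#' time points; direction chosen per protein), a fraction is ON (control
#' channel absent: detected only under treatment, at all time points) and a
#' fraction OFF (treated channel absent at one random time point).
#' Peptide-level log2 ratios are the protein log2 ratio plus Gaussian noise.
#'
#' @param n_proteins Number of proteins.
#' @param frac_regulated Fraction with a planted fold change.
#' @param effect_fc Planted fold change (> 1).
#' @param peptides_per_protein Peptides (spectra) per protein.
#' @param noise_sd_log2 SD of peptide-level log2-ratio noise.
#' @param frac_on,frac_off Fractions of ON / OFF proteins (default 0).
#' @param seed RNG seed.
#' @return An `itraq_experiment`: list with `proteins`, `true_ratio`
#'   (matrix proteins x time points), `onoff_truth` (character matrix,
#'   "normal"/"ON"/"OFF"), `truth_significant` (logical matrix: planted
#'   effect or ON/OFF), `spectra` (named list of `isotope_pattern`s, one
#'   per peptide), `peptide_map` (peptide -> protein), `templates`, `seed`.
#' @export
gen_itraq_experiment <- function(n_proteins, frac_regulated = 0.1,
                                 effect_fc = 3, peptides_per_protein = 3,
                                 noise_sd_log2 = 0.3, frac_on = 0.02,
                                 frac_off = 0.02, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (effect_fc <= 0) stop("effect_fc must be positive", call. = FALSE)
  fr <- c(frac_regulated, frac_on, frac_off)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("fractions must lie in [0,1] and sum to at most 1", call. = FALSE)
  }
  if (frac_regulated > 0 && effect_fc <= 1) {
    stop("effect_fc must exceed 1 when proteins are regulated", call. = FALSE)
  }
  local_seed(seed, {
    prot <- syn_accessions(n_proteins)
    n_reg <- round(frac_regulated * n_proteins)
    n_on <- round(frac_on * n_proteins)
    n_off <- round(frac_off * n_proteins)
    special <- sample(prot, n_reg + n_on + n_off)
    regulated <- special[seq_len(n_reg)]
    on_prot <- special[n_reg + seq_len(n_on)]
    off_prot <- special[n_reg + n_on + seq_len(n_off)]
    true_ratio <- matrix(1, n_proteins, 3, dimnames = list(prot, TIMEPOINTS))
    onoff <- matrix("normal", n_proteins, 3, dimnames = list(prot, TIMEPOINTS))
    for (p in regulated) {
      dir <- sample(c(1, -1), 1)
      tps <- sample(3, sample(3, 1))
      true_ratio[p, tps] <- effect_fc^dir
    }
    onoff[on_prot, ] <- "ON"
    for (p in off_prot) onoff[p, sample(3, 1)] <- "OFF"
    templates <- reporter_templates()
    spectra <- list(); peptide_map <- character()
    for (p in prot) {
      for (j in seq_len(peptides_per_protein)) {
        pep <- sprintf("%s_pep%d", p, j)
        treated <- true_ratio[p, ] *
          2^stats::rnorm(3, 0, noise_sd_log2)
        ctrl <- 1
        if (all(onoff[p, ] == "ON")) ctrl <- 0
        treated[onoff[p, ] == "OFF"] <- 0
        amp <- stats::runif(1, 0.5, 2)
        spectra[[pep]] <- gen_reporter_spectrum(amp * c(ctrl, treated), templates)
        peptide_map[pep] <- p
      }
    }
    truth_sig <- (true_ratio != 1) | (onoff != "normal")
    structure(
      list(proteins = prot, true_ratio = true_ratio, onoff_truth = onoff,
           truth_significant = truth_sig, regulated = regulated,
           on_proteins = on_prot, off_proteins = off_prot,
           spectra = spectra, peptide_map = peptide_map,
           templates = templates, seed = seed),
      class = "itraq_experiment"
    )
  })
}

#' Generate a connected interactome fixture with annotated terms and
#' planted targets
#'
#' Builds a connected random graph (random spanning tree plus extra random
#' edges), annotation terms whose node sets induce connected subgraphs
#' (grown by randomised breadth-first expansion), and a target set with
#' known placement: roughly half the targets sit inside a term (direct),
#' the rest are neighbours of a term (peripheral) where available.
#' Affinities are uniform in (0, 1] with the maximum pinned to 1.
#'
#' @param n_nodes,n_edges Graph size (requires `n_edges >= n_nodes - 1` and
#'   at most `choose(n_nodes, 2)`).
#' @param n_terms Number of annotation terms.
#' @param term_size Nodes per term (at most `n_nodes`).
#' @param n_targets Number of drug targets to place.
#' @param seed RNG seed.
#' @return A `network_fixture`: list with `graph` (igraph), `term2nodes`,
#'   `targets` (named affinities), `placement` (data frame: node, relation,
#'   term), `seed`.
#' @export
gen_network_fixture <- function(n_nodes, n_edges, n_terms, term_size,
                                n_targets, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_edges < n_nodes - 1 || n_edges > choose(n_nodes, 2)) {
    stop("n_edges must allow a connected simple graph", call. = FALSE)
  }
  if (term_size > n_nodes) stop("term_size exceeds n_nodes", call. = FALSE)
  if (n_targets > n_nodes) stop("n_targets exceeds n_nodes", call. = FALSE)
  local_seed(seed, {
    nodes <- syn_accessions(n_nodes, prefix = "N")
    # random spanning tree: attach each node to a random earlier node
    edges <- cbind(2:n_nodes, vapply(2:n_nodes, function(i) sample.int(i - 1, 1), 1L))
    have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    while (nrow(edges) < n_edges) {
      cand <- sort(sample.int(n_nodes, 2))
      key <- paste(cand[1], cand[2])
      if (!(key %in% have)) {
        edges <- rbind(edges, cand)
        have <- c(have, key)
      }
    }
    g <- igraph::graph_from_edgelist(
      cbind(nodes[edges[, 1]], nodes[edges[, 2]]), directed = FALSE)
    # connected term node sets by randomised BFS growth
    term2nodes <- list()
    for (k in seq_len(n_terms)) {
      s <- sample(nodes, 1)
      set <- s
      while (length(set) < term_size) {
        frontier <- setdiff(unique(unlist(
          igraph::adjacent_vertices(g, set), use.names = FALSE)), match(set, nodes))
        frontier <- nodes[frontier]
        if (length(frontier) == 0L) break
        set <- c(set, sample(frontier, 1))
      }
      term2nodes[[sprintf("TERM%02d", k)]] <- set
    }
    placement <- data.frame(node = character(), relation = character(),
                            term = character(), stringsAsFactors = FALSE)
    if (n_targets > 0) {
      n_direct <- ceiling(n_targets / 2)
      pool_direct <- unique(unlist(term2nodes))
      direct <- sample(pool_direct, min(n_direct, length(pool_direct)))
      for (d in direct) {
        tm <- names(term2nodes)[vapply(term2nodes, function(s) d %in% s, TRUE)][1]
        placement <- rbind(placement, data.frame(
          node = d, relation = "direct", term = tm, stringsAsFactors = FALSE))
      }
      n_left <- n_targets - length(direct)
      if (n_left > 0) {
        nb <- unique(unlist(lapply(term2nodes, function(s) {
          setdiff(nodes[unique(unlist(igraph::adjacent_vertices(g, s),
                                      use.names = FALSE))], s)
        })))
        nb <- setdiff(nb, direct)
        periph <- sample(nb, min(n_left, length(nb)))
        for (p in periph) {
          placement <- rbind(placement, data.frame(
            node = p, relation = "peripheral", term = NA_character_,
            stringsAsFactors = FALSE))
        }
        n_left <- n_left - length(periph)
        if (n_left > 0) {
          extra <- sample(setdiff(nodes, placement$node), n_left)
          placement <- rbind(placement, data.frame(
            node = extra, relation = "random", term = NA_character_,
            stringsAsFactors = FALSE))
        }
      }
      aff <- stats::runif(nrow(placement), 0.2, 1)
      aff <- aff / max(aff)
      targets <- stats::setNames(aff, placement$node)
    } else {
      targets <- stats::setNames(numeric(0), character(0))
    }
    structure(
      list(graph = g, term2nodes = term2nodes, targets = targets,
           placement = placement, seed = seed),
      class = "network_fixture"
    )
  })
}
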