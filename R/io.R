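# Readers and writers for the plain-text formats the pipeline touches:
# TSV tables, SIF edge lists, protein FASTA, and two-column spectra.

#' Write a table as TSV
#'
#' UTF-8, tab-separated, header row, "." decimal separator, no quoting;
#' missing values as empty cells.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a network from a SIF or two-column edge file
#'
#' SIF lines are `nodeA <relation> nodeB`; two-column files are plain edge
#' lists. Self-loops and duplicate edges are dropped.
#'
#' @param path Input path.
#' @return Undirected [igraph::graph] with named vertices.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  el <- t(vapply(parts, function(p) {
    if (length(p) == 3) p[c(1, 3)]
    else if (length(p) == 2) p
    else stop("malformed SIF/edge line: ", paste(p, collapse = " "), call. = FALSE)
  }, character(2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as SIF
#'
#' @param graph An [igraph::graph] with named vertices.
#' @param path Output path.
#' @param relation Interaction type token (default "pp").
#' @export
write_sif <- function(graph, path, relation = "pp") {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], relation, el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Input path.
#' @return Named character vector of sequences; names are the first token
#'   of each header line.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  id <- sub("^>(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("[ \t]", "", paste(x, collapse = "")),
                 character(1))
  stats::setNames(toupper(unname(seqs)), id)
}

#' Write protein sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60) {
  out <- unlist(lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column (m/z, intensity) spectrum
#' @param path Input path (TSV with header).
#' @return An `isotope_pattern` (intensities as stored, not normalised).
#' @export
read_spectrum_tsv <- function(path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2) stop("spectrum file needs (m/z, intensity) columns: ", path,
                          call. = FALSE)
  new_isotope_pattern(grid = as.numeric(tab[[1]]), intensity = as.numeric(tab[[2]]))
}

#' Write a spectrum as two-column TSV
#' @param spectrum An `isotope_pattern`.
#' @param path Output path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  write_tsv(data.frame(mz = spectrum$grid, intensity = spectrum$intensity), path)
}
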