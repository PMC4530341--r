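#' Read a gene expression matrix
#'
#' Tab-separated text with gene identifiers in the first column and a
#' header row of sample identifiers; values are log-scale expression.
#' Rows sharing a gene identifier are collapsed by their mean (with a
#' message), matching the convention that duplicate probes summarise to
#' one gene-level row.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix (genes x samples) with unique row and column
#'   names; all values finite.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus >= 1 sample")
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, sample_ids)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite cell at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  rownames(num) <- gene_ids
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    message(sprintf("collapsing %d duplicated gene id(s) by mean: %s",
                    length(dups), paste(head(dups, 5L), collapse = ", ")))
    num <- rowsum(num, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  }
  validate_expression(num)
  num
}

validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  if (!all(is.finite(mat))) stop("expression values must all be finite")
  invisible(mat)
}

#' Write an expression matrix
#'
#' @param mat numeric genes x samples matrix with dimnames.
#' @param path output TSV path.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction network
#'
#' Accepts a two-column tab-separated edge list, or SIF
#' (`node<TAB>relation<TAB>node`). Reversed and repeated edges are
#' merged; self-loops are dropped with a warning.
#'
#' @param path path to the network file.
#' @param format `"auto"` (three columns means SIF), `"edgelist"` or
#'   `"sif"`.
#' @return An [interaction_network()].
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") format <- if (all(nf >= 3L)) "sif" else "edgelist"
  if (format == "edgelist") {
    if (any(nf < 2L)) stop("edge-list line with fewer than two columns")
    edges <- t(vapply(fields, function(f) f[c(1L, 2L)], character(2L)))
  } else {
    if (any(nf < 3L)) stop("SIF line with fewer than three columns")
    edges <- t(vapply(fields, function(f) f[c(1L, 3L)], character(2L)))
  }
  interaction_network(edges)
}

#' Write an interaction network as a SIF file
#'
#' @param network an `interaction_network`.
#' @param path output path.
#' @param relation relation label for the middle SIF column.
#' @export
write_network_sif <- function(network, path, relation = "pp") {
  e <- network$edges
  writeLines(if (nrow(e)) paste(e[, 1L], relation, e[, 2L], sep = "\t")
             else character(), path)
  invisible(path)
}

#' Read a survival annotation table
#'
#' Expects tab-separated columns `sample_id`, `time`, `event`. Time is
#' the distant metastasis-free survival time (months, > 0); event is 1
#' for an observed metastasis and 0 for censoring.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sample_id` (character), `time`
#'   (numeric) and `event` (integer 0/1).
#' @export
read_survival <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  validate_survival(out)
  out
}

validate_survival <- function(surv) {
  if (anyDuplicated(surv$sample_id)) stop("duplicate sample id in survival table")
  if (any(!is.finite(surv$time)) || any(surv$time <= 0))
    stop("survival time must be finite and > 0")
  if (!all(surv$event %in% c(0L, 1L)))
    stop("event indicator must be 0 or 1")
  invisible(surv)
}

#' Write a survival annotation table
#'
#' @param surv data.frame as returned by [read_survival()].
#' @param path output TSV path.
#' @export
write_survival <- function(surv, path) {
  validate_survival(surv)
  write.table(surv[, c("sample_id", "time", "event")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated. Set names must be unique and every set non-empty.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (the member genes), with a
#'   `descriptions` attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("GMT line %d has fewer than 3 fields (name, description, >= 1 gene)",
                 bad[1L]))
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  descs <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- names_
  structure(sets, descriptions = setNames(descs, names_),
            class = "gene_set_collection")
}

#' Write subnetworks to JSON (plus per-subnetwork SIF files)
#'
#' Each subnetwork record carries members, seed, raw p-value, score S,
#' FDR-adjusted p and the Cox coefficient beta. When `network` is given,
#' one SIF file with each subnetwork's induced edges is written next to
#' the JSON. [read_subnetworks()] restores the list exactly.
#'
#' @param spns list of subnetworks (see [greedy_search()]).
#' @param path output JSON path.
#' @param network optional `interaction_network` used for the SIF files.
#' @return `path`, invisibly.
#' @export
write_subnetworks <- function(spns, path, network = NULL) {
  recs <- lapply(spns, function(s) {
    list(members = as.list(sort(s$members)), seed = s$seed,
         raw_p = s$raw_p, score_s = s$score_s,
         adjusted_p = if (is.null(s$adjusted_p)) NA else s$adjusted_p,
         beta = s$beta)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(network) && length(spns) > 0L) {
    base <- sub("\\.json$", "", path)
    for (i in seq_along(spns)) {
      e <- induced_edges(network, spns[[i]]$members)
      sif <- sprintf("%s_spn%02d.sif", base, i)
      writeLines(if (nrow(e)) paste(e[, 1L], "pp", e[, 2L], sep = "\t")
                 else character(), sif)
    }
  }
  invisible(path)
}

#' Read subnetworks back from JSON
#'
#' @param path JSON path written by [write_subnetworks()].
#' @return List of subnetwork records.
#' @export
read_subnetworks <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    list(members = sort(unlist(r$members, use.names = FALSE)),
         seed = r$seed,
         raw_p = as.numeric(r$raw_p),
         score_s = as.numeric(r$score_s),
         adjusted_p = if (is.null(r$adjusted_p)) NA_real_ else as.numeric(r$adjusted_p),
         beta = as.numeric(r$beta))
  })
}
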