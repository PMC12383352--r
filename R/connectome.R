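#' @useDynLib connstage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm prcomp rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils head tail
NULL

#' Canonical stage labels
#'
#' The three ordered stages of clinical cognitive decline handled by the
#' package: `G0` (SCI-like), `G1` (MCI-like), `G2` (ADD-like).
#'
#' @return Character vector of the three canonical group labels, ordered
#'   from earliest to latest stage.
#' @export
stage_labels <- function() c("G0", "G1", "G2")

default_region_labels <- function(n) {
  sprintf("region_%03d", seq_len(n) - 1L)
}

#' Packaged 148-region cortical label table
#'
#' Convenience table of 148 bilateral region names in the style of a
#' standard surface-based cortical parcellation, usable as `region_labels`
#' for 148-node connectomes. The pipeline never depends on specific names;
#' generic zero-padded labels are the default everywhere.
#'
#' @return Character vector of 148 labels ordered by node index (0-147).
#' @export
region_label_table <- function() {
  path <- system.file("extdata", "parcellation_148_labels.tsv",
                      package = "connstage")
  utils::read.delim(path, stringsAsFactors = FALSE)$region_label
}

#' Construct a connectome
#'
#' A connectome is one subject's weighted structural brain network: a
#' symmetric, nonnegative, zero-diagonal `N x N` matrix of edge weights
#' (e.g. normalized streamline counts between cortical parcels), together
#' with a subject id, a stage label and region names.
#'
#' @param weights Square numeric matrix; symmetric, nonnegative, zero
#'   diagonal.
#' @param subject_id Character scalar.
#' @param group One of [stage_labels()].
#' @param region_labels Character vector of length `nrow(weights)`;
#'   defaults to zero-padded generic names (`region_000`, ...).
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, subject_id = "subject", group = "G0",
                       region_labels = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(weights))
  obj <- structure(
    list(subject_id = as.character(subject_id),
         group = as.character(group),
         weights = unname(weights),
         region_labels = as.character(region_labels)),
    class = "connectome"
  )
  validate_connectome(obj)
  obj
}

#' Validate connectome invariants
#'
#' Checks squareness, symmetry (tolerance `1e-8`), nonnegativity, zero
#' diagonal and label length. Each violation is reported as a distinct
#' error naming the offending cell in 0-based node indices.
#'
#' @param x A `connectome`.
#' @param tol Symmetry tolerance.
#' @return `x`, invisibly.
#' @export
validate_connectome <- function(x, tol = 1e-8) {
  w <- x$weights
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop("weights must be a square matrix, got ", nrow(w), " x ", ncol(w))
  }
  n <- nrow(w)
  if (anyNA(w) || any(!is.finite(w))) {
    bad <- which(!is.finite(w), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite weight at cell (%d,%d)", bad[1] - 1L, bad[2] - 1L))
  }
  asym <- abs(w - t(w))
  if (any(asym > tol)) {
    bad <- which(asym > tol, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    i <- bad[1, 1] - 1L; j <- bad[1, 2] - 1L
    stop(sprintf("asymmetric weights at cell (%d,%d)/(%d,%d): %g vs %g",
                 i, j, j, i, w[i + 1L, j + 1L], w[j + 1L, i + 1L]))
  }
  if (any(w < 0)) {
    bad <- which(w < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative weight at cell (%d,%d): %g",
                 bad[1] - 1L, bad[2] - 1L, w[bad[1], bad[2]]))
  }
  d <- diag(w)
  if (any(d != 0)) {
    k <- which(d != 0)[1]
    stop(sprintf("nonzero diagonal at cell (%d,%d): %g", k - 1L, k - 1L, d[k]))
  }
  if (length(x$region_labels) != n) {
    stop("region_labels length ", length(x$region_labels),
         " does not match matrix size ", n)
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> subject %s (group %s): %d regions, %d positive edges\n",
              x$subject_id, x$group, n, ne))
  invisible(x)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a connectome adjacency matrix from delimited text
#'
#' Parses an `N x N` numeric grid (CSV or TSV; comma/tab auto-detected
#' when `delimiter` is `NULL`) and validates the connectome invariants.
#'
#' @param path File path.
#' @param delimiter Field delimiter, or `NULL` to auto-detect.
#' @param subject_id,group Metadata attached to the result.
#' @param region_labels Optional region names; generic names by default.
#' @return A [connectome()].
#' @export
read_adjacency <- function(path, delimiter = NULL, subject_id = NULL,
                           group = "G0", region_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  dt <- data.table::fread(path, sep = delimiter, header = FALSE,
                          colClasses = "numeric", data.table = FALSE)
  w <- as.matrix(dt)
  if (nrow(w) != ncol(w)) {
    stop("non-square grid in ", path, ": ", nrow(w), " rows x ", ncol(w), " columns")
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  connectome(w, subject_id = subject_id, group = group,
             region_labels = region_labels)
}

#' Write a connectome adjacency matrix to comma-delimited text
#'
#' Round-trips losslessly: `read_adjacency(write_adjacency(c))` reproduces
#' the weights to `1e-12` (full-precision formatting).
#'
#' @param connectome A [connectome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(connectome, path) {
  validate_connectome(connectome)
  data.table::fwrite(as.data.frame(connectome$weights), file = path,
                     sep = ",", col.names = FALSE)
  invisible(path)
}

#' Binarize a connectome
#'
#' Converts weighted edges to presence/absence: `adjacency[i,j] = 1` iff
#' `weights[i,j] > threshold`. Node features are the one-hot encoding of
#' node indices (the `N x N` identity), the input representation consumed
#' by the graph encoder.
#'
#' @param connectome A [connectome()].
#' @param threshold Nonnegative weight threshold; default 0 ("presence of
#'   fibers" = strictly positive weight).
#' @return An object of class `binarized_graph` with fields `adjacency`
#'   (0/1 matrix), `features` (identity matrix), `subject_id`, `group`.
#' @export
binarize <- function(connectome, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single nonnegative number")
  }
  validate_connectome(connectome)
  n <- nrow(connectome$weights)
  adj <- (connectome$weights > threshold) * 1
  structure(
    list(adjacency = adj, features = diag(n),
         subject_id = connectome$subject_id, group = connectome$group),
    class = "binarized_graph"
  )
}

#' @export
print.binarized_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("<binarized_graph> subject %s (group %s): %d nodes, %d edges\n",
              x$subject_id, x$group, n, sum(x$adjacency[upper.tri(x$adjacency)])))
  invisible(x)
}

#' Load a dataset manifest and its connectomes
#'
#' The manifest is a TSV with header columns `subject_id`, `group`,
#' `path` (paths resolved relative to the manifest's directory unless
#' absolute). Subject ids must be unique, groups must be canonical stage
#' labels, and all matrices must share the same node count.
#'
#' @param path Manifest file path.
#' @return A list with `manifest` (data.frame) and `connectomes` (list of
#'   [connectome()] in manifest order).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           colClasses = "character")
  req <- c("subject_id", "group", "path")
  if (!all(req %in% names(man))) {
    stop("manifest must have header columns subject_id, group, path")
  }
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup)) stop("duplicate subject_id in manifest: ", dup[1])
  bad <- setdiff(unique(man$group), stage_labels())
  if (length(bad)) {
    stop("unknown group label '", bad[1], "'; expected one of ",
         paste(stage_labels(), collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  cns <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    cns[[i]] <- read_adjacency(p, subject_id = man$subject_id[i],
                               group = man$group[i])
  }
  ns <- vapply(cns, function(c) nrow(c$weights), integer(1))
  if (length(unique(ns)) > 1L) {
    stop("node-count mismatch across manifest files: found sizes ",
         paste(unique(ns), collapse = ", "))
  }
  list(manifest = man, connectomes = cns)
}

#' Write a cohort of connectomes plus manifest to a directory
#'
#' One comma-delimited adjacency file per subject and a `manifest.tsv`
#' with columns `subject_id`, `group`, `path`.
#'
#' @param cohort List of [connectome()].
#' @param dir Output directory (created if missing).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(cn) {
    f <- paste0(cn$subject_id, ".csv")
    write_adjacency(cn, file.path(dir, f))
    data.frame(subject_id = cn$subject_id, group = cn$group, path = f,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  data.table::fwrite(man, mpath, sep = "\t")
  invisible(mpath)
}
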