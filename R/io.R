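#' Canonical Gordon resting-state network labels
#'
#' The 12 network names of the Gordon 333-parcel cortical atlas, used
#' throughout for atlas validation and virtual lesioning: AUD (auditory),
#' CO (cingulo-opercular), CP (cingulo-parietal), DAN (dorsal attention),
#' DMN (default mode), FPN (frontoparietal), RSP (retrosplenial), SAL
#' (salience), SM (somatomotor), SML (lateral somatomotor), VAN (ventral
#' attention), VIS (visual). Parcels outside these networks carry the label
#' `"UNASSIGNED"`; they participate in modeling but cannot be lesioned.
#'
#' @format Character vector of length 12.
#' @export
gordon_networks <- c("AUD", "CO", "CP", "DAN", "DMN", "FPN",
                     "RSP", "SAL", "SM", "SML", "VAN", "VIS")

#' Upper-triangle edge index for P parcels
#'
#' Enumerates all unordered parcel pairs (i, j), i < j, in row-major
#' (lexicographic) order. This ordering defines the edge axis of every
#' edge matrix in the package. Parcel indices are 0-based, matching the
#' on-disk atlas convention.
#'
#' @param n_parcels Number of parcels P.
#' @return A data.frame with integer columns `i` and `j` (0-based) and
#'   `n_parcels * (n_parcels - 1) / 2` rows.
#' @export
edge_pairs <- function(n_parcels) {
  p <- as.integer(n_parcels)
  if (is.na(p) || p < 2L) stop("n_parcels must be an integer >= 2")
  i <- rep.int(0:(p - 2L), (p - 1L):1L)
  j <- sequence((p - 1L):1L) + i
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Flattens a symmetric P x P connectivity matrix into its
#' `P*(P-1)/2` off-diagonal upper-triangle entries in row-major order
#' (pair (0,1), (0,2), ..., (1,2), ...). The diagonal is discarded.
#'
#' @param mat Square numeric matrix, symmetric within `tol`.
#' @param tol Absolute symmetry tolerance (default 1e-8). Asymmetry beyond
#'   this is a format error naming the offending entry.
#' @return Numeric vector of length `P*(P-1)/2`.
#' @seealso [devectorize()] for the inverse.
#' @export
vectorize_upper <- function(mat, tol = 1e-8) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("connectivity matrix must be square")
  if (!all(is.finite(mat)))
    stop("connectivity matrix contains non-finite values")
  d <- abs(mat - t(mat))
  if (any(d > tol)) {
    bad <- which(d == max(d), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix not symmetric within tol=%g: entry (%d,%d)=%g vs (%d,%d)=%g",
      tol, bad[1L], bad[2L], mat[bad[1L], bad[2L]],
      bad[2L], bad[1L], mat[bad[2L], bad[1L]]))
  }
  t(mat)[lower.tri(mat)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()]: places the edge vector back into a
#' symmetric P x P matrix with zero diagonal.
#'
#' @param v Edge vector of length `P*(P-1)/2` for some integer P.
#' @return Symmetric numeric P x P matrix.
#' @export
devectorize <- function(v) {
  e <- length(v)
  p <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(p - round(p)) > 1e-9)
    stop(sprintf("length %d is not P*(P-1)/2 for integer P", e))
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v          # row-major upper == column-major lower of t()
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Construct a connectome set
#'
#' A connectome set holds N subjects' vectorized functional-connectivity
#' matrices as an N x E edge matrix, E = P*(P-1)/2, with edge order defined
#' by [edge_pairs()].
#'
#' @param edges N x E numeric matrix; all values must be finite.
#' @param subject_ids Character vector of N unique subject identifiers.
#' @param n_parcels Parcel count P consistent with E.
#' @return An object of class `connectome_set`.
#' @export
connectome_set <- function(edges, subject_ids, n_parcels) {
  .assert_numeric_matrix(edges)
  p <- as.integer(n_parcels)
  if (ncol(edges) != p * (p - 1L) / 2L)
    stop(sprintf("edge count %d != P*(P-1)/2 for P=%d", ncol(edges), p))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(edges)) stop("one subject id per row required")
  if (anyDuplicated(subject_ids))
    stop("duplicated subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  rownames(edges) <- subject_ids
  structure(list(subject_ids = subject_ids, edges = edges, n_parcels = p),
            class = "connectome_set")
}

#' @export
print.connectome_set <- function(x, ...) {
  cat(sprintf("<connectome_set> %d subjects, %d parcels, %d edges\n",
              length(x$subject_ids), x$n_parcels, ncol(x$edges)))
  invisible(x)
}

#' Construct a parcel-to-network atlas
#'
#' @param parcel_id Integer parcel ids, 0-based, one per parcel, unique.
#' @param network Character labels; each must be one of [gordon_networks]
#'   or `"UNASSIGNED"`.
#' @return A `network_atlas` data.frame sorted by `parcel_id`.
#' @export
network_atlas <- function(parcel_id, network) {
  parcel_id <- as.integer(parcel_id)
  network <- as.character(network)
  if (length(parcel_id) != length(network)) stop("parcel_id/network length mismatch")
  if (anyDuplicated(parcel_id)) stop("duplicated parcel ids in atlas")
  bad <- setdiff(unique(network), c(gordon_networks, "UNASSIGNED"))
  if (length(bad))
    stop("unknown network label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(parcel_id = parcel_id, network = network)
  out <- out[order(out$parcel_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("network_atlas", "data.frame")
  out
}

#' Edges incident to a network
#'
#' Returns the indices (positions along the edge axis) of all edges with at
#' least one endpoint in the named network — the edge set a virtual lesion
#' of that network removes. With `within_only = TRUE` only edges with both
#' endpoints inside the network are returned.
#'
#' Atlas rows are matched to matrix rows/columns by ascending `parcel_id`,
#' so the k-th smallest parcel id labels the k-th parcel of the
#' connectivity matrices.
#'
#' @param atlas A [network_atlas()].
#' @param label One of [gordon_networks]. `"UNASSIGNED"` is not a
#'   lesionable target and raises an error.
#' @param within_only Logical; restrict to within-network edges.
#' @return Sorted integer vector of 1-based edge positions.
#' @export
edges_of_network <- function(atlas, label, within_only = FALSE) {
  stopifnot(inherits(atlas, "network_atlas"))
  if (!is.character(label) || length(label) != 1L || !label %in% gordon_networks)
    stop("label must be one of the 12 canonical networks (UNASSIGNED cannot be lesioned): ",
         paste(gordon_networks, collapse = ", "))
  members <- which(atlas$network == label) - 1L   # 0-based positions
  if (!length(members))
    stop(sprintf("atlas has no parcel labeled %s", label))
  ep <- edge_pairs(nrow(atlas))
  hit <- if (within_only) (ep$i %in% members) & (ep$j %in% members)
         else (ep$i %in% members) | (ep$j %in% members)
  which(hit)
}

# ---- reading / writing ------------------------------------------------------

.read_delim <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA", ...)
}

#' Read a connectome set
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{edge table}{a single tab-delimited file: column `subject_id`
#'     followed by one column per edge named `e<i>_<j>` (0-based parcel
#'     pair), in the row-major upper-triangle order of [edge_pairs()].}
#'   \item{matrix directory}{a directory of per-subject tab-delimited
#'     P x P symmetric matrices, filename `<subject_id>.tsv`.}
#' }
#'
#' @param path File (edge table) or directory (matrices).
#' @param tol Symmetry tolerance forwarded to [vectorize_upper()].
#' @return A [connectome_set()].
#' @export
read_connectomes <- function(path, tol = 1e-8) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) stop("no .tsv connectivity matrices in ", path)
    ids <- sub("\\.tsv$", "", basename(files))
    rows <- lapply(files, function(f) {
      m <- as.matrix(utils::read.table(f, header = FALSE, sep = "\t"))
      dimnames(m) <- NULL
      vectorize_upper(m, tol = tol)
    })
    p <- (1 + sqrt(1 + 8 * length(rows[[1L]]))) / 2
    return(connectome_set(do.call(rbind, rows), ids, as.integer(round(p))))
  }
  if (!file.exists(path)) stop("connectome source not found: ", path)
  tab <- .read_delim(path)
  if (names(tab)[1L] != "subject_id") stop("edge table must start with subject_id")
  ids <- as.character(tab$subject_id)
  edges <- as.matrix(tab[, -1L, drop = FALSE])
  got <- colnames(edges)
  e <- ncol(edges)
  p <- as.integer(round((1 + sqrt(1 + 8 * e)) / 2))
  ep <- edge_pairs(p)
  want <- sprintf("e%d_%d", ep$i, ep$j)
  if (!identical(got, want)) {
    if (all(want %in% got)) edges <- edges[, want, drop = FALSE]
    else stop("edge table header does not enumerate the upper triangle for P=", p)
  }
  storage.mode(edges) <- "double"
  colnames(edges) <- NULL
  connectome_set(edges, ids, p)
}

#' Write a connectome set
#'
#' @param cs A [connectome_set()].
#' @param path Output file (`format = "edges"`) or directory
#'   (`format = "matrix"`).
#' @param format `"edges"` (single edge table) or `"matrix"` (one symmetric
#'   matrix file per subject). Values are written with 17 significant
#'   digits so a write/read round trip is lossless.
#' @export
write_connectomes <- function(cs, path, format = c("edges", "matrix")) {
  stopifnot(inherits(cs, "connectome_set"))
  format <- match.arg(format)
  if (format == "edges") {
    ep <- edge_pairs(cs$n_parcels)
    chr <- matrix(.fmt_num(cs$edges), nrow = nrow(cs$edges))
    tab <- cbind(subject_id = cs$subject_ids, as.data.frame(chr))
    names(tab) <- c("subject_id", sprintf("e%d_%d", ep$i, ep$j))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(cs$subject_ids)) {
      m <- devectorize(cs$edges[k, ])
      utils::write.table(matrix(.fmt_num(m), nrow = nrow(m)),
                         file.path(path, paste0(cs$subject_ids[k], ".tsv")),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a parcel-to-network atlas table
#'
#' Expects tab-delimited text with header columns `parcel_id` and `network`.
#'
#' @param path Atlas file.
#' @return A [network_atlas()].
#' @export
read_atlas <- function(path) {
  tab <- .read_delim(path)
  if (!all(c("parcel_id", "network") %in% names(tab)))
    stop("atlas must have columns parcel_id and network")
  network_atlas(tab$parcel_id, tab$network)
}

#' @rdname read_atlas
#' @param atlas A [network_atlas()] to write.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral/covariate table
#'
#' Tab-delimited text with a mandatory `subject_id` column; remaining
#' columns are outcomes and covariates. Missing values use the literal
#' token `NA`. Duplicated subject ids are an error.
#'
#' @param path Behavior file.
#' @return A data.frame.
#' @export
read_behavior <- function(path) {
  tab <- .read_delim(path)
  if (!"subject_id" %in% names(tab)) stop("behavior table needs a subject_id column")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject id(s) in behavior table: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  tab
}

#' @rdname read_behavior
#' @param behavior Behavior data.frame to write (numeric columns are written
#'   at full precision).
#' @export
write_behavior <- function(behavior, path) {
  out <- behavior
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and join the three input artifacts
#'
#' Reads connectomes, atlas and behavior, verifies that the atlas covers
#' every parcel and that subject ids match one-to-one between connectomes
#' and behavior (mismatches are an error listing the offending ids, never a
#' silent drop), reorders behavior rows to the connectome order, and logs a
#' one-line summary.
#'
#' @param connectome_source Edge-table file or matrix directory
#'   (see [read_connectomes()]).
#' @param atlas_path Atlas file.
#' @param behavior_path Behavior file.
#' @param outcomes Optional character vector of outcome columns that must be
#'   present and complete (no missing values).
#' @return `list(connectomes, atlas, behavior)`.
#' @export
read_inputs <- function(connectome_source, atlas_path, behavior_path,
                        outcomes = NULL) {
  cs <- read_connectomes(connectome_source)
  atlas <- read_atlas(atlas_path)
  beh <- read_behavior(behavior_path)
  if (nrow(atlas) != cs$n_parcels)
    stop(sprintf("atlas has %d parcels but connectomes have %d",
                 nrow(atlas), cs$n_parcels))
  only_beh <- setdiff(beh$subject_id, cs$subject_ids)
  only_con <- setdiff(cs$subject_ids, beh$subject_id)
  if (length(only_beh) || length(only_con))
    stop("subject id mismatch between behavior and connectomes; ",
         "behavior-only: [", paste(only_beh, collapse = ", "),
         "]; connectome-only: [", paste(only_con, collapse = ", "), "]")
  beh <- beh[match(cs$subject_ids, beh$subject_id), , drop = FALSE]
  rownames(beh) <- NULL
  if (!is.null(outcomes)) {
    miss <- setdiff(outcomes, names(beh))
    if (length(miss)) stop("outcome column(s) missing: ", paste(miss, collapse = ", "))
    for (o in outcomes)
      if (anyNA(beh[[o]]))
        stop("outcome ", o, " has missing values for modeled subjects")
  }
  message(sprintf("read_inputs: N=%d subjects, P=%d parcels, E=%d edges, outcomes: %s",
                  length(cs$subject_ids), cs$n_parcels, ncol(cs$edges),
                  paste(setdiff(names(beh), "subject_id"), collapse = ", ")))
  list(connectomes = cs, atlas = atlas, behavior = beh)
}
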