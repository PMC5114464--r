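#' Rooted vascular tree
#'
#' A `vascular_tree` is a rooted graph of vessel segments stored as a
#' one-row-per-segment table with parent pointers. Radii and lengths are in
#' millimetres; cross-sectional areas are computed on demand as \eqn{\pi r^2}
#' (circular cross-section). Optional per-segment labels: `territory`
#' (perfused epicardial territory, e.g. LAD/LCx/RCA), `transmural_depth`
#' (normalized 0 = epicardium to 1 = endocardium) and `weibel_generation`.
#'
#' @param segments data.frame with columns `id`, `parent` (NA for the root),
#'   `radius_mm`, `length_mm` and any optional label columns.
#' @param validate logical; run structural validation (default `TRUE`).
#' @param tree a `vascular_tree` (accessor functions).
#' @return An object of class `vascular_tree`: the segment table plus a
#'   `root_id` attribute.
#' @examples
#' seg <- data.frame(id = c("m", "a", "b"), parent = c(NA, "m", "m"),
#'                   radius_mm = c(1, 0.8, 0.6), length_mm = c(10, 8, 6))
#' tr <- vascular_tree(seg)
#' n_segments(tr)
#' @export
vascular_tree <- function(segments, validate = TRUE) {
  stopifnot(is.data.frame(segments))
  required <- c("id", "parent", "radius_mm", "length_mm")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  segments$id <- as.character(segments$id)
  segments$parent <- as.character(segments$parent)
  segments$parent[!is.na(segments$parent) & segments$parent == ""] <- NA
  rownames(segments) <- NULL
  tree <- structure(list(segments = segments,
                         root_id = segments$id[is.na(segments$parent)][1]),
                    class = "vascular_tree")
  if (validate) validate_tree(tree)
  tree
}

#' Validate a vascular tree
#'
#' Checks: unique ids, exactly one root, every parent pointer resolves,
#' acyclicity/connectedness, positive radii and lengths, and
#' `transmural_depth` in \[0, 1\] where present. Errors name the offending row.
#'
#' @param tree a `vascular_tree`.
#' @return `tree`, invisibly, if valid.
#' @export
validate_tree <- function(tree) {
  seg <- tree$segments
  if (anyDuplicated(seg$id)) {
    stop("duplicated segment id(s): ",
         paste(unique(seg$id[duplicated(seg$id)]), collapse = ", "))
  }
  roots <- which(is.na(seg$parent))
  if (length(roots) != 1) {
    stop("tree must have exactly one root (row with empty parent); found ",
         length(roots),
         if (length(roots) > 0)
           paste0(": rows ", paste(roots, collapse = ", ")) else "")
  }
  bad <- which(!is.na(seg$parent) & !(seg$parent %in% seg$id))
  if (length(bad) > 0) {
    stop("unresolved parent id for segment(s) ",
         paste(seg$id[bad], collapse = ", "), " (row ",
         paste(bad, collapse = ", "), ")")
  }
  bad <- which(!is.finite(seg$radius_mm) | seg$radius_mm <= 0)
  if (length(bad) > 0) {
    stop("nonpositive radius for segment(s) ",
         paste(seg$id[bad], collapse = ", "), " (row ",
         paste(bad, collapse = ", "), ")")
  }
  bad <- which(!is.finite(seg$length_mm) | seg$length_mm <= 0)
  if (length(bad) > 0) {
    stop("nonpositive length for segment(s) ",
         paste(seg$id[bad], collapse = ", "), " (row ",
         paste(bad, collapse = ", "), ")")
  }
  if ("transmural_depth" %in% names(seg)) {
    d <- seg$transmural_depth
    bad <- which(!is.na(d) & (d < 0 | d > 1))
    if (length(bad) > 0) {
      stop("transmural_depth outside [0, 1] for segment(s) ",
           paste(seg$id[bad], collapse = ", "))
    }
  }
  # connectivity / acyclicity: every segment must reach the root by
  # following parent pointers without revisiting a node
  idx <- match(seg$parent, seg$id)
  reached <- is.na(seg$parent)  # root
  frontier <- which(reached)
  while (length(frontier) > 0) {
    nxt <- which(!reached & idx %in% frontier)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reached)) {
    stop("segment(s) not connected to the root (cycle or orphan): ",
         paste(seg$id[!reached], collapse = ", "))
  }
  invisible(tree)
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat("<vascular_tree> ", nrow(x$segments), " segments, root '", x$root_id,
      "'\n", sep = "")
  cat("  radius range: ",
      paste(signif(range(x$segments$radius_mm), 3), collapse = " - "),
      " mm\n", sep = "")
  extra <- setdiff(names(x$segments),
                   c("id", "parent", "radius_mm", "length_mm"))
  if (length(extra) > 0) cat("  labels:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname vascular_tree
#' @export
n_segments <- function(tree) nrow(tree$segments)

#' Cross-sectional areas of tree segments
#'
#' @param tree a `vascular_tree`.
#' @return numeric vector of areas in mm^2, in segment-table order.
#' @export
segment_areas <- function(tree) pi * tree$segments$radius_mm^2

#' Read a vascular tree from a plain-text node table
#'
#' The on-disk format is comma-separated with one row per segment:
#' `id,parent,radius_mm,length_mm[,territory,transmural_depth,...]`. The root
#' row has an empty `parent` field. Unknown columns are preserved as labels.
#'
#' @param path path to the table. Lines starting with `#` are ignored.
#' @param edge_convention only `"parent"` (implicit edge list through parent
#'   pointers) is supported.
#' @return a validated `vascular_tree`.
#' @export
load_tree <- function(path, edge_convention = "parent") {
  edge_convention <- match.arg(edge_convention, "parent")
  if (!file.exists(path)) stop("file not found: ", path)
  seg <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(id = "character",
                                        parent = "character"))
  vascular_tree(seg)
}

#' Write a vascular tree to a plain-text node table
#'
#' Columns are written in deterministic order (`id`, `parent`, `radius_mm`,
#' `length_mm`, then remaining label columns alphabetically); numeric fields
#' keep full double precision so that `load_tree(save_tree(x))` round-trips
#' exactly.
#'
#' @param tree a `vascular_tree`.
#' @param path output path.
#' @param header_comment optional character vector written as leading `#`
#'   comment lines (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path, header_comment = NULL) {
  seg <- tree$segments
  fixed <- c("id", "parent", "radius_mm", "length_mm")
  extra <- sort(setdiff(names(seg), fixed))
  seg <- seg[, c(fixed, extra), drop = FALSE]
  out <- seg
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  out$parent[is.na(seg$parent)] <- ""
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# children lookup: list mapping id -> integer row indices of children
.children_index <- function(tree) {
  seg <- tree$segments
  split(seq_len(nrow(seg))[!is.na(seg$parent)],
        factor(seg$parent[!is.na(seg$parent)], levels = seg$id))
}

#' Extract bifurcation records and the junction census
#'
#' One record is produced for every node with exactly two children. For each
#' the area ratio \eqn{\sigma = (A_{d1}+A_{d2})/A_m} and symmetry ratio
#' \eqn{\gamma = A_{d2}/A_{d1} \in (0,1]} are computed, with daughters ordered
#' so that \eqn{A_{d1} \ge A_{d2}} (ties broken by id). Junctions with three
#' or more children (trifurcations and higher) are counted in the census and
#' excluded from the records, mirroring standard practice for coronary
#' morphometry where they are rare (~4% of junctions).
#'
#' @param tree a `vascular_tree`.
#' @return list with class `bifurcation_set`:
#'   \item{records}{data.frame, one row per bifurcation: ids, areas (mm^2),
#'     `sigma`, `gamma`, mother radius `r_m` and inherited labels}
#'   \item{census}{named list: counts of `terminal`, `unary`, `bifurcation`,
#'     `nfurcation` nodes, fractions over all nodes, and
#'     `junction_fractions` among nodes with >= 2 children}
#' @export
extract_bifurcations <- function(tree) {
  validate_tree(tree)
  seg <- tree$segments
  kids <- .children_index(tree)
  nkids <- lengths(kids)
  counts <- c(terminal = sum(nkids == 0),
              unary = sum(nkids == 1),
              bifurcation = sum(nkids == 2),
              nfurcation = sum(nkids >= 3))
  n_junc <- counts[["bifurcation"]] + counts[["nfurcation"]]
  census <- list(
    counts = as.list(counts),
    fractions = as.list(counts / nrow(seg)),
    junction_fractions = list(
      bifurcation = if (n_junc > 0) counts[["bifurcation"]] / n_junc else NA,
      nfurcation = if (n_junc > 0) counts[["nfurcation"]] / n_junc else NA))
  bif_rows <- which(nkids == 2)
  if (length(bif_rows) == 0) {
    records <- data.frame(mother_id = character(), d1_id = character(),
                          d2_id = character(), A_m = numeric(),
                          A_d1 = numeric(), A_d2 = numeric(),
                          sigma = numeric(), gamma = numeric(),
                          r_m = numeric())
  } else {
    mother_ids <- names(kids)[bif_rows]
    m_idx <- match(mother_ids, seg$id)
    c1 <- vapply(kids[bif_rows], `[`, integer(1), 1L)
    c2 <- vapply(kids[bif_rows], `[`, integer(1), 2L)
    a1 <- pi * seg$radius_mm[c1]^2
    a2 <- pi * seg$radius_mm[c2]^2
    # order so that A_d1 >= A_d2; on exact ties order by id for determinism
    swap <- a1 < a2 | (a1 == a2 & seg$id[c1] > seg$id[c2])
    d1 <- ifelse(swap, c2, c1)
    d2 <- ifelse(swap, c1, c2)
    A_d1 <- pi * seg$radius_mm[d1]^2
    A_d2 <- pi * seg$radius_mm[d2]^2
    A_m <- pi * seg$radius_mm[m_idx]^2
    records <- data.frame(
      mother_id = seg$id[m_idx], d1_id = seg$id[d1], d2_id = seg$id[d2],
      A_m = A_m, A_d1 = A_d1, A_d2 = A_d2,
      sigma = (A_d1 + A_d2) / A_m, gamma = A_d2 / A_d1,
      r_m = seg$radius_mm[m_idx], stringsAsFactors = FALSE)
    for (lab in c("territory", "transmural_depth", "weibel_generation",
                  "transmural_layer")) {
      if (lab %in% names(seg)) records[[lab]] <- seg[[lab]][m_idx]
    }
    rownames(records) <- NULL
  }
  structure(list(records = records, census = census),
            class = "bifurcation_set")
}

#' @export
print.bifurcation_set <- function(x, ...) {
  cat("<bifurcation_set> ", nrow(x$records), " bifurcations\n", sep = "")
  cts <- x$census$counts
  cat(sprintf("  census: %d terminal, %d unary, %d bifurcation, %d n-furcation\n",
              cts$terminal, cts$unary, cts$bifurcation, cts$nfurcation))
  invisible(x)
}

#' Assign Weibel generation numbers
#'
#' Generation numbering starts at 1 for the daughters of the first junction
#' and increases by 1 at every junction (node with >= 2 children) crossed on
#' the root-to-segment path. Segments proximal to the first junction
#' (including the root) get generation 0. Unary pass-through nodes do not
#' increment the counter.
#'
#' @param tree a `vascular_tree`.
#' @return the tree with a `weibel_generation` integer column filled.
#' @export
assign_weibel_generations <- function(tree) {
  seg <- tree$segments
  n <- nrow(seg)
  idx_parent <- match(seg$parent, seg$id)
  nkids <- tabulate(idx_parent, nbins = n)
  gen <- integer(n)
  root_row <- match(tree$root_id, seg$id)
  in_frontier <- logical(n)
  in_frontier[root_row] <- TRUE
  while (any(in_frontier)) {
    child <- which(!is.na(idx_parent) & in_frontier[idx_parent])
    gen[child] <- gen[idx_parent[child]] +
      as.integer(nkids[idx_parent[child]] >= 2)
    in_frontier <- logical(n)
    in_frontier[child] <- TRUE
  }
  tree$segments$weibel_generation <- gen
  tree
}

# bin a normalized depth in [0,1] into n equal-width layers; depth 1.0 falls
# in the last layer
.bin_depth <- function(depth, n_layers) {
  pmin(floor(depth * n_layers) + 1L, n_layers)
}

#' Assign transmural layers
#'
#' Bins the normalized transmural depth (0 = epicardium, 1 = endocardium)
#' into `n_layers` equal-width layers; the boundary value 1.0 is assigned to
#' the last (subendocardial) layer.
#'
#' @param tree a `vascular_tree` with a `transmural_depth` column.
#' @param n_layers number of equal layers (default 3).
#' @return the tree with an integer `transmural_layer` column.
#' @export
assign_transmural_layer <- function(tree, n_layers = 3) {
  seg <- tree$segments
  if (!("transmural_depth" %in% names(seg)) ||
      all(is.na(seg$transmural_depth))) {
    stop("tree has no transmural_depth labels; cannot assign layers")
  }
  tree$segments$transmural_layer <- .bin_depth(seg$transmural_depth, n_layers)
  tree
}
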