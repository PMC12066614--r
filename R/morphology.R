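#' @importFrom rlang %||%
#' @importFrom stats approx
NULL

SWC_KIND_MAP <- c("1" = "soma", "2" = "axon", "3" = "basal_dendrite",
                  "4" = "apical_dendrite")

swc_kind <- function(code) {
  k <- SWC_KIND_MAP[as.character(code)]
  ifelse(is.na(k), "connector", k)
}

kind_swc_code <- function(kind) {
  code <- match(kind, SWC_KIND_MAP)
  ifelse(is.na(code), 5L, code)
}

# Cumulative arclength at the vertices of a polyline geometry matrix
# (columns x, y, z, diam).
polyline_arclength <- function(g) {
  if (nrow(g) < 2) return(0)
  d <- sqrt(rowSums(diff(g[, 1:3, drop = FALSE])^2))
  unname(c(0, cumsum(d)))
}

# Position and diameter at arclengths s along a polyline geometry.
interp_along <- function(g, s) {
  cl <- polyline_arclength(g)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  cbind(
    x = approx(cl, g[, 1], s, ties = "ordered")$y,
    y = approx(cl, g[, 2], s, ties = "ordered")$y,
    z = approx(cl, g[, 3], s, ties = "ordered")$y,
    diam = approx(cl, g[, 4], s, ties = "ordered")$y
  )
}

#' Build a morphology from a section table
#'
#' A morphology is a tree of unbranched cable sections; each section carries
#' a 3D polyline geometry with per-point diameters and is discretised into
#' `nseg` segments of equal arclength whose centre points ("nodes") hold all
#' compartmental biophysics. The default discretisation is two segments per
#' section.
#'
#' @param sections A data frame with columns `section_id` (integer),
#'   `parent_id` (integer, `NA` for the root), `kind` (one of `"soma"`,
#'   `"axon"`, `"basal_dendrite"`, `"apical_dendrite"`, `"connector"`) and a
#'   list column `geometry` of numeric matrices with columns x, y, z, diam
#'   (um); optionally `nseg`.
#' @param nseg_default Segments per section where `nseg` is absent
#'   (default 2).
#' @return An object of class `morphology` with elements `sections`
#'   (tibble, including computed `length_um`) and `segments` (tibble with
#'   one row per node: `node_id`, `section_id`, `seg_index`, `kind`, `x`,
#'   `y`, `z`, `length_um`, `diameter_um`, `arclength_um`).
#' @export
morphology <- function(sections, nseg_default = 2) {
  sections <- tibble::as_tibble(sections)
  stopifnot(all(c("section_id", "parent_id", "kind", "geometry") %in%
                  names(sections)))
  if (!"nseg" %in% names(sections)) sections$nseg <- as.integer(nseg_default)
  sections$nseg[is.na(sections$nseg)] <- as.integer(nseg_default)
  for (g in sections$geometry) {
    if (!is.matrix(g) || nrow(g) < 2 || ncol(g) < 4) {
      stop("each geometry must be a matrix with >= 2 rows and columns x, y, z, diam",
           call. = FALSE)
    }
    if (any(g[, 4] <= 0)) stop("diameters must be > 0", call. = FALSE)
  }
  sections$length_um <- vapply(sections$geometry, function(g) {
    cl <- polyline_arclength(g)
    cl[length(cl)]
  }, numeric(1))
  validate_section_tree(sections)
  m <- structure(list(sections = sections), class = "morphology")
  m$segments <- build_segments(m, nseg_default)
  m
}

validate_section_tree <- function(sections) {
  ids <- sections$section_id
  if (anyDuplicated(ids)) stop("duplicate section ids", call. = FALSE)
  roots <- which(is.na(sections$parent_id))
  if (length(roots) != 1) {
    stop(sprintf("morphology must have exactly one root section (found %d)",
                 length(roots)), call. = FALSE)
  }
  orphan <- !is.na(sections$parent_id) & !(sections$parent_id %in% ids)
  if (any(orphan)) {
    stop(sprintf("section %d refers to missing parent %d",
                 ids[which(orphan)[1]],
                 sections$parent_id[which(orphan)[1]]), call. = FALSE)
  }
  # cycle check: every section must reach the root
  parent_of <- stats::setNames(sections$parent_id, ids)
  for (id in ids) {
    seen <- integer(0)
    cur <- id
    while (!is.na(parent_of[[as.character(cur)]])) {
      if (cur %in% seen) stop("section parent links contain a cycle",
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  invisible(TRUE)
}

#' Discretise sections into segments
#'
#' Splits each section into `nseg` segments of equal arclength; the node of
#' segment i sits at arclength `(i - 1/2) * L / nseg` from the section start,
#' positioned by linear interpolation along the geometry polyline.
#'
#' @param morph A [morphology()] (or the bare section tibble wrapped in one).
#' @param nseg_default Segments per section when a section does not specify
#'   `nseg`.
#' @return A tibble of segments (see [morphology()]).
#' @export
build_segments <- function(morph, nseg_default = 2) {
  stopifnot(nseg_default >= 1)
  sections <- morph$sections
  segs <- purrr::pmap(
    list(sections$section_id, sections$kind, sections$geometry,
         sections$nseg %||% rep(nseg_default, nrow(sections))),
    function(sid, kind, g, nseg) {
      nseg <- as.integer(nseg %||% nseg_default)
      cl <- polyline_arclength(g)
      L <- cl[length(cl)]
      mid <- (seq_len(nseg) - 0.5) * L / nseg
      p <- interp_along(g, mid)
      tibble::tibble(
        section_id = sid, seg_index = seq_len(nseg), kind = kind,
        x = p[, "x"], y = p[, "y"], z = p[, "z"],
        length_um = L / nseg, diameter_um = p[, "diam"],
        arclength_um = mid
      )
    })
  out <- dplyr::bind_rows(segs)
  out$node_id <- seq_len(nrow(out))
  dplyr::relocate(out, "node_id")
}

#' @export
print.morphology <- function(x, ...) {
  kinds <- table(x$sections$kind)
  cat(sprintf("<morphology> %d sections, %d segments\n",
              nrow(x$sections), nrow(x$segments)))
  cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, 1-based ids, parent
#' -1 for the root, radius in um). Points are grouped into unbranched
#' sections, splitting at branch points and at type changes; type codes map
#' 1 to soma, 2 to axon, 3 to basal dendrite, 4 to apical dendrite, anything
#' else to connector. A child section's geometry is prefixed with its
#' junction point so that sections connect end-to-start.
#'
#' @param path SWC file path.
#' @param nseg_default Segments per section (default 2).
#' @return A [morphology()].
#' @export
read_swc <- function(path, nseg_default = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, comment.char = "#",
                      col.names = c("id", "type", "x", "y", "z", "radius",
                                    "parent"),
                      colClasses = "numeric"),
    error = function(e) stop("malformed SWC file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0) stop("SWC file '", path, "' has no points",
                           call. = FALSE)
  if (any(tab$radius <= 0)) {
    stop(sprintf("SWC line with id %d has non-positive radius",
                 tab$id[which(tab$radius <= 0)[1]]), call. = FALSE)
  }
  idx <- match(tab$parent, tab$id)  # NA for roots (-1)
  orphan <- which(tab$parent != -1 & is.na(idx))
  if (length(orphan) > 0) {
    stop(sprintf("SWC point %d refers to missing parent %d",
                 tab$id[orphan[1]], tab$parent[orphan[1]]), call. = FALSE)
  }
  n <- nrow(tab)
  nchildren <- tabulate(idx[!is.na(idx)], nbins = n)
  child_of <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  # A section starts at a root point, at a child of a branch point, or where
  # the type changes from the parent's type.
  starts <- which(is.na(idx) | nchildren[idx] > 1 |
                    tab$type != tab$type[idx])
  sec_rows <- list()
  sec_of_point <- integer(n)
  for (k in seq_along(starts)) {
    chain <- starts[k]
    repeat {
      last <- chain[length(chain)]
      kids <- child_of[[last]]
      if (length(kids) != 1) break
      if (tab$type[kids] != tab$type[starts[k]]) break
      if (kids %in% starts) break
      chain <- c(chain, kids)
    }
    sec_of_point[chain] <- k
    sec_rows[[k]] <- chain
  }
  # a single-point root whose type continues in a child section is spliced
  # into that child (the child's junction-prefixed geometry already holds
  # the root point); a single-point root with no same-type continuation is
  # a spherical soma, expanded to an equivalent cylinder
  root_k <- which(vapply(sec_rows, function(ch) is.na(idx[ch[1]]),
                         logical(1)))
  merge_child <- NA_integer_
  if (length(sec_rows[[root_k]]) == 1) {
    cand <- which(vapply(seq_along(starts), function(k) {
      k != root_k &&
        sec_of_point[idx[sec_rows[[k]][1]]] == root_k &&
        tab$type[sec_rows[[k]][1]] == tab$type[sec_rows[[root_k]][1]]
    }, logical(1)))
    if (length(cand) > 0) merge_child <- cand[1]
  }
  secs <- purrr::map(seq_along(starts), function(k) {
    if (!is.na(merge_child) && k == root_k) return(NULL)
    chain <- sec_rows[[k]]
    p <- idx[chain[1]]
    g <- as.matrix(cbind(tab$x[chain], tab$y[chain], tab$z[chain],
                         2 * tab$radius[chain]))
    if (!is.na(p)) {
      g <- rbind(c(tab$x[p], tab$y[p], tab$z[p], 2 * tab$radius[p]), g)
    } else if (nrow(g) == 1) {
      r <- tab$radius[chain]
      g <- rbind(c(tab$x[chain] - r, tab$y[chain], tab$z[chain], 2 * r),
                 c(tab$x[chain] + r, tab$y[chain], tab$z[chain], 2 * r))
    }
    dimnames(g) <- list(NULL, c("x", "y", "z", "diam"))
    parent <- if (is.na(p)) NA_integer_ else sec_of_point[p]
    if (!is.na(merge_child)) {
      if (k == merge_child) {
        parent <- NA_integer_
      } else if (!is.na(parent) && parent == root_k) {
        parent <- merge_child
      }
    }
    tibble::tibble(
      section_id = k, parent_id = parent,
      kind = swc_kind(tab$type[chain[1]]),
      geometry = list(g)
    )
  })
  morphology(dplyr::bind_rows(secs), nseg_default = nseg_default)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]: emits one SWC point per geometry vertex, skipping
#' each non-root section's junction point (owned by its parent), so that a
#' write/read round trip preserves coordinates exactly.
#'
#' @param morph A [morphology()].
#' @param path Output path.
#' @export
write_swc <- function(morph, path) {
  secs <- morph$sections
  lines <- character(0)
  next_id <- 1L
  sec_point_ids <- vector("list", nrow(secs))   # SWC ids per section vertex
  # parents must be written before children: order by tree depth
  depth <- section_depths(secs)
  for (i in order(depth)) {
    g <- secs$geometry[[i]]
    pid <- secs$parent_id[i]
    if (is.na(pid)) {
      rows <- seq_len(nrow(g))
      prev <- -1L
    } else {
      # attach at the parent's vertex coinciding with this section's
      # junction point (sections may branch off anywhere on the parent)
      pi_ <- match(pid, secs$section_id)
      pg <- secs$geometry[[pi_]]
      d2 <- colSums((t(pg[, 1:3, drop = FALSE]) - g[1, 1:3])^2)
      j <- which.min(d2)
      if (d2[j] < 1e-12) {
        rows <- seq(2, nrow(g))
        prev <- sec_point_ids[[pi_]][j]
      } else {
        rows <- seq_len(nrow(g))
        prev <- sec_point_ids[[pi_]][j]
      }
    }
    ids <- integer(nrow(g))
    if (length(rows) < nrow(g)) ids[1] <- NA_integer_
    for (r in rows) {
      lines <- c(lines, sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                                next_id, kind_swc_code(secs$kind[i]),
                                g[r, 1], g[r, 2], g[r, 3], g[r, 4] / 2, prev))
      ids[r] <- next_id
      prev <- next_id
      next_id <- next_id + 1L
    }
    sec_point_ids[[i]] <- ids
  }
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

section_depths <- function(secs) {
  depth <- rep(NA_integer_, nrow(secs))
  depth[is.na(secs$parent_id)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    for (i in todo) {
      pd <- depth[match(secs$parent_id[i], secs$section_id)]
      if (!is.na(pd)) depth[i] <- pd + 1L
    }
  }
  depth
}

#' Axon path with cumulative arclength
#'
#' Orders the axonal segments root-outward and returns their nodes with the
#' cumulative arclength measured from the axon origin (the axon section
#' whose parent is not an axon).
#'
#' @param morph A [morphology()].
#' @return A tibble `(node_id, section_id, seg_index, arclength_um, x, y, z)`
#'   with strictly increasing `arclength_um` along each axonal branch.
#' @export
axon_path <- function(morph) {
  secs <- morph$sections
  ax <- secs$section_id[secs$kind == "axon"]
  if (length(ax) == 0) stop("morphology has no axon section", call. = FALSE)
  parent <- stats::setNames(secs$parent_id, secs$section_id)
  kind <- stats::setNames(secs$kind, secs$section_id)
  len <- stats::setNames(secs$length_um, secs$section_id)
  origin <- ax[vapply(ax, function(id) {
    p <- parent[[as.character(id)]]
    is.na(p) || kind[[as.character(p)]] != "axon"
  }, logical(1))]
  # start offset (arclength of the section start within the axon path)
  offset <- stats::setNames(rep(NA_real_, length(ax)), ax)
  queue <- origin
  offset[as.character(origin)] <- 0
  ordered <- integer(0)
  while (length(queue) > 0) {
    id <- queue[1]; queue <- queue[-1]
    ordered <- c(ordered, id)
    kids <- ax[!is.na(parent[as.character(ax)]) &
                 parent[as.character(ax)] == id]
    if (length(kids) > 0) {
      offset[as.character(kids)] <- offset[[as.character(id)]] +
        len[[as.character(id)]]
      queue <- c(queue, kids)
    }
  }
  segs <- morph$segments[morph$segments$kind == "axon", ]
  segs <- segs[order(match(segs$section_id, ordered), segs$seg_index), ]
  segs$arclength_um <- unname(offset[as.character(segs$section_id)]) +
    segs$arclength_um
  tibble::as_tibble(segs[c("node_id", "section_id", "seg_index",
                           "arclength_um", "x", "y", "z")])
}

#' Dense sample points along the axon
#'
#' Resamples the axon geometry (ordered root-outward) at a uniform arclength
#' step, for extracellular-potential profiles and activating-function
#' analysis.
#'
#' @param morph A [morphology()].
#' @param step Sampling step (um).
#' @param range Optional arclength window `c(lo, hi)` (um); default the full
#'   axon.
#' @return A tibble `(arclength_um, x, y, z)`.
#' @export
sample_axon_line <- function(morph, step = 0.01, range = NULL) {
  secs <- morph$sections
  ax_nodes <- axon_path(morph)
  sec_order <- unique(ax_nodes$section_id)
  pts <- NULL
  off <- 0
  for (sid in sec_order) {
    g <- secs$geometry[[match(sid, secs$section_id)]]
    cl <- polyline_arclength(g)
    p <- cbind(arclength_um = off + cl, g[, 1:3, drop = FALSE])
    if (!is.null(pts)) p <- p[-1, , drop = FALSE]  # drop duplicated junction
    pts <- rbind(pts, p)
    off <- off + cl[length(cl)]
  }
  lo <- if (is.null(range)) 0 else max(0, range[1])
  hi <- if (is.null(range)) off else min(off, range[2])
  s <- seq(lo, hi, by = step)
  tibble::tibble(
    arclength_um = s,
    x = approx(pts[, 1], pts[, 2], s, ties = "ordered")$y,
    y = approx(pts[, 1], pts[, 3], s, ties = "ordered")$y,
    z = approx(pts[, 1], pts[, 4], s, ties = "ordered")$y
  )
}

#' Nearest segment of a given kind
#'
#' Returns the segment whose node is closest (Euclidean) to a query
#' position, restricted to the given compartment kinds; ties break toward
#' the lowest section id, then the lowest segment index.
#'
#' @param morph A [morphology()].
#' @param position Numeric length-3 query point (um).
#' @param kinds Character vector of allowed kinds (default all).
#' @return A one-row tibble from `morph$segments`.
#' @export
nearest_segment <- function(morph, position,
                            kinds = unique(morph$segments$kind)) {
  stopifnot(length(kinds) >= 1)
  segs <- morph$segments[morph$segments$kind %in% kinds, ]
  if (nrow(segs) == 0) {
    stop("no segment of kind ", paste(kinds, collapse = "/"), call. = FALSE)
  }
  d2 <- (segs$x - position[1])^2 + (segs$y - position[2])^2 +
    (segs$z - position[3])^2
  segs <- segs[order(d2, segs$section_id, segs$seg_index), ]
  segs[1, ]
}

# Segment-graph edges: consecutive segments within a section, plus the first
# segment of each child section to the parent segment whose node is nearest
# the child's junction point (children can attach anywhere on the parent,
# e.g. axon and basal dendrites at the soma base).
segment_edges <- function(morph) {
  segs <- morph$segments
  secs <- morph$sections
  edges <- NULL
  for (i in seq_len(nrow(secs))) {
    sid <- secs$section_id[i]
    nodes <- segs$node_id[segs$section_id == sid]
    if (length(nodes) > 1) {
      edges <- rbind(edges, cbind(nodes[-length(nodes)], nodes[-1]))
    }
    pid <- secs$parent_id[i]
    if (!is.na(pid)) {
      junction <- secs$geometry[[i]][1, 1:3]
      psub <- segs[segs$section_id == pid, ]
      d2 <- (psub$x - junction[1])^2 + (psub$y - junction[2])^2 +
        (psub$z - junction[3])^2
      edges <- rbind(edges, cbind(psub$node_id[which.min(d2)], nodes[1]))
    }
  }
  edges
}

#' Per-section summary table
#'
#' @param morph A [morphology()].
#' @return A tibble `(section_id, kind, length_um, parent_id, nseg)`.
#' @export
section_summary <- function(morph) {
  tibble::as_tibble(morph$sections[c("section_id", "kind", "length_um",
                                     "parent_id", "nseg")])
}

#' @rdname section_summary
#' @param path Output CSV path.
#' @export
write_section_summary <- function(morph, path) {
  utils::write.csv(section_summary(morph), path, row.names = FALSE)
  invisible(path)
}
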