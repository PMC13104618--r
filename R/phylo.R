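#' Convert a percent-similarity matrix to evolutionary-style distances
#'
#' `d = (100 - similarity) / 100`, so 100% similarity maps to distance 0
#' and 10% to 0.9. The diagonal is forced to zero.
#'
#' @param sim A `SimilarityMatrix`.
#' @return A `DistanceMatrix` (fields `ids`, `values`).
#' @export
to_distance <- function(sim) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  d <- (100 - sim$values) / 100
  diag(d) <- 0
  structure(list(ids = sim$ids, values = d), class = "DistanceMatrix")
}

#' @noRd
as_distance_matrix <- function(d) {
  if (inherits(d, "DistanceMatrix")) return(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.matrix(d)) {
    ids <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
    return(structure(list(ids = ids, values = unname(d)),
                     class = "DistanceMatrix"))
  }
  stop("cannot interpret input as a distance matrix", call. = FALSE)
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("<DistanceMatrix>", length(x$ids), "taxa\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration on the Q criterion, terminating at
#' the three-taxon star (two-taxon input yields a single split edge).
#' Negative intermediate branch lengths are clamped to zero with a
#' warning. The agglomeration is deterministic: among pairs tying on Q,
#' the pair whose (sorted) representative leaf labels are
#' lexicographically smallest is joined. NJ is exact on additive
#' distances: it recovers the generating topology and edge lengths.
#'
#' @param d A `DistanceMatrix` (or square symmetric matrix / `dist`).
#' @return An unrooted `ape::phylo` tree with the input ids as tip
#'   labels.
#' @export
neighbor_joining <- function(d) {
  d <- as_distance_matrix(d)
  vals <- d$values
  n <- length(d$ids)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (!isTRUE(all.equal(vals, t(vals), tolerance = 1e-12)))
    stop("distance matrix is not symmetric", call. = FALSE)
  clamp <- function(x) {
    if (x < 0) {
      warning("negative branch length clamped to 0", call. = FALSE)
      return(0)
    }
    x
  }
  fmt <- function(x) sprintf("%.15g", x)
  # active nodes: newick fragment + representative (smallest leaf) label;
  # leaves enter as placeholder tokens so arbitrary ids survive parsing
  nwk <- paste0("L", seq_along(d$ids))
  rep_lab <- d$ids
  D <- vals
  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - li)
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":",
                      fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  txt <- if (length(nwk) == 2L) {
    paste0("(", nwk[1L], ":", fmt(clamp(D[1L, 2L] / 2)), ",", nwk[2L], ":",
           fmt(clamp(D[1L, 2L] / 2)), ");")
  } else {
    la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    paste0("(", nwk[1L], ":", fmt(la), ",", nwk[2L], ":", fmt(lb), ",",
           nwk[3L], ":", fmt(lc), ");")
  }
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- d$ids[as.integer(sub("^L", "", tr$tip.label))]
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path,
#' subdividing the edge on which the midpoint falls (the new root has
#' degree 2). Ties on path length are broken by the lexicographically
#' smallest sorted leaf-label pair. Degree-2 internal nodes of the input
#' (e.g. a previous root) are spliced out first, so rooting is idempotent
#' up to relabeling.
#'
#' @param tree An `ape::phylo` tree (rooted or unrooted) with edge
#'   lengths.
#' @return A rooted `ape::phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 leaves", call. = FALSE)
  adj <- tree_adjacency(tree)
  labels <- tree$tip.label
  # single-source distances + predecessors on the spliced graph
  sssp <- function(src) {
    nn <- length(adj)
    dist <- rep(NA_real_, nn)
    pred <- rep(NA_integer_, nn)
    dist[src] <- 0
    stack <- src
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- adj[[u]]
      for (k in seq_len(NROW(nb))) {
        v <- nb[k, 1L]
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + nb[k, 2L]
          pred[v] <- u
          stack <- c(stack, v)
        }
      }
    }
    list(dist = dist, pred = pred)
  }
  paths <- lapply(seq_len(ntip), sssp)
  best <- -Inf
  bi <- bj <- 1L
  for (i in seq_len(ntip - 1L)) {
    for (j in seq.int(i + 1L, ntip)) {
      dij <- paths[[i]]$dist[j]
      if (dij > best + 1e-12) {
        best <- dij; bi <- i; bj <- j
      } else if (abs(dij - best) <= 1e-12) {
        old <- sort(c(labels[bi], labels[bj]))
        new <- sort(c(labels[i], labels[j]))
        if (paste(new, collapse = "\r") < paste(old, collapse = "\r")) {
          bi <- i; bj <- j
        }
      }
    }
  }
  # node path bi -> bj from the predecessor chain of bi's search
  path <- bj
  while (path[1L] != bi) path <- c(paths[[bi]]$pred[path[1L]], path)
  target <- best / 2
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    len <- paths[[bi]]$dist[v] - paths[[bi]]$dist[u]
    if (cum + len >= target - 1e-12) {
      pos <- target - cum  # distance from u along (u, v)
      return(reroot_on_edge(adj, labels, u, v, pos))
    }
    cum <- cum + len
  }
  stop("midpoint not found; tree may lack edge lengths", call. = FALSE)
}

# Undirected adjacency list (with degree-2 nodes spliced out), keyed by
# ape node number.
#' @noRd
tree_adjacency <- function(tree) {
  nnode <- max(tree$edge)
  adj <- vector("list", nnode)
  el <- tree$edge.length %||% rep(1, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, el[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, el[e]))
  }
  ntip <- length(tree$tip.label)
  # splice out degree-2 nodes (internal only)
  repeat {
    deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x),
                  integer(1L))
    two <- which(deg == 2L & seq_len(nnode) > ntip)
    if (!length(two)) break
    v <- two[1L]
    nb <- adj[[v]]
    a <- nb[1L, 1L]; b <- nb[2L, 1L]
    len <- nb[1L, 2L] + nb[2L, 2L]
    adj[[a]] <- adj[[a]][adj[[a]][, 1L] != v, , drop = FALSE]
    adj[[b]] <- adj[[b]][adj[[b]][, 1L] != v, , drop = FALSE]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
    adj[v] <- list(NULL)
  }
  adj
}

# Build a rooted tree with the root inserted on edge (u, v) at distance
# pos from u, via a rooted Newick rendering of the adjacency list.
#' @noRd
reroot_on_edge <- function(adj, labels, u, v, pos) {
  ntip <- length(labels)
  # (u, v) from nodepath may pass through spliced degree-2 nodes; find the
  # actual adjacency edge between surviving nodes containing u or v
  edge_len <- function(a, b) {
    nb <- adj[[a]]
    hit <- which(nb[, 1L] == b)
    if (length(hit)) nb[hit[1L], 2L] else NA_real_
  }
  fmt <- function(x) sprintf("%.15g", x)
  subtree <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1L] != parent, , drop = FALSE]
    lab <- if (node <= ntip) paste0("L", node) else ""
    if (node <= ntip && nrow(kids) == 0L) return(lab)
    paste0("(", paste(vapply(seq_len(nrow(kids)), function(k) {
      paste0(subtree(kids[k, 1L], node), ":", fmt(kids[k, 2L]))
    }, character(1L)), collapse = ","), ")", lab)
  }
  len <- edge_len(u, v)
  if (is.na(len)) {
    # u..v not a direct edge after splicing; walk from u toward v through
    # the adjacency graph accumulating pos (can only happen when the old
    # root sat on this path). Fall back to direct neighbors of u.
    stop("internal error: midpoint edge not in adjacency", call. = FALSE)
  }
  lu <- pos
  lv <- len - pos
  txt <- paste0("(", subtree(u, v), ":", fmt(lu), ",", subtree(v, u), ":",
                fmt(lv), ");")
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- labels[as.integer(sub("^L", "", tr$tip.label))]
  tr
}

#' @noRd
newick_quote <- function(label) {
  if (grepl("[^A-Za-z0-9_.-]", label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

#' Serialize a tree as Newick text
#'
#' Branch lengths are written with 6 significant digits; labels
#' containing characters outside `[A-Za-z0-9_.-]` are single-quoted.
#'
#' @param tree An `ape::phylo` tree.
#' @return A single Newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  el <- tree$edge.length
  fmt <- function(x) sprintf("%.6g", x)
  kids_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
  render <- function(node) {
    es <- kids_of[[as.character(node)]]
    lab <- if (node <= ntip) newick_quote(tree$tip.label[node]) else ""
    if (is.null(es)) return(lab)
    paste0("(", paste(vapply(es, function(e) {
      paste0(render(tree$edge[e, 2L]),
             if (!is.null(el)) paste0(":", fmt(el[e])) else "")
    }, character(1L)), collapse = ","), ")", lab)
  }
  paste0(render(root), ";")
}

#' Write tree-viewer annotation metadata
#'
#' Emits a CSV joining typing results with plasmid metadata, one row per
#' tree leaf, for annotating exported trees in external viewers.
#'
#' @param typing Typing table from [type_corpus()].
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param path Output CSV path.
#' @export
write_tree_annotations <- function(typing, metadata, path) {
  m <- metadata[match(typing$plasmid_id, metadata$plasmid_id), , drop = FALSE]
  carb <- if ("carbapenemases" %in% names(m))
    vapply(m$carbapenemases, function(x)
      paste(x, collapse = ";"), character(1L))
  else ""
  df <- data.frame(id = typing$record_id, family = typing$family,
                   subclade = typing$subclade,
                   host_genus = if ("host_genus" %in% names(m))
                     m$host_genus else NA_character_,
                   carbapenemase = carb, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
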