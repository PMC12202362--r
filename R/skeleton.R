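#' Skeletonize a binary vessel mask
#'
#' Topology-preserving thinning (Zhang–Suen) to a one-pixel-wide,
#' 8-connected medial curve. The skeleton is always a subset of the input
#' mask and the operation is idempotent on its own output.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  cpp_thin(m) != 0L
}

# 8-neighborhood offsets, fixed order.
NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Decompose a skeleton into a node/edge graph
#'
#' Nodes are skeleton pixels with one neighbor (endpoints), three or
#' more (branch points), or none (isolated pixels); edges are the simple
#' pixel paths between nodes, and every remaining pixel (degree exactly
#' 2) belongs to exactly one edge path. Adjacency is the reduced
#' 8-connectivity: a diagonal link is ignored whenever an orthogonal
#' skeleton pixel already bridges the pair, which prevents the staircase
#' patterns of thinned skeletons from reading as spurious junctions.
#' Pure cycles with no node are cut at their lexicographically smallest
#' pixel (row, then column) and flagged as loops.
#'
#' @param skeleton Logical matrix (one-pixel-wide skeleton).
#' @return A `skeleton_graph`: list with `nodes` (data.frame: r, c,
#'   degree, type) and `edges` (list of paths; each a list with `path`
#'   (n x 2 matrix of (r, c) pixel indices) and `is_loop`).
#' @export
skeleton_graph <- function(skeleton) {
  stopifnot(is.matrix(skeleton))
  skel <- skeleton != 0
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- cpp_reduced_degree(matrix(as.integer(skel), nr, nc))
  px <- which(skel, arr.ind = TRUE)
  if (nrow(px) == 0)
    return(structure(list(nodes = data.frame(r = integer(), c = integer(),
                                             degree = integer(),
                                             type = character()),
                          edges = list(), dim = c(nr, nc)),
                     class = "skeleton_graph"))
  # order pixels lexicographically by (row, col)
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  pd <- deg[px]
  is_node_m <- matrix(FALSE, nr, nc)
  node_sel <- pd != 2L
  is_node_m[px[node_sel, , drop = FALSE]] <- TRUE
  nodes <- data.frame(r = px[node_sel, 1], c = px[node_sel, 2],
                      degree = pd[node_sel],
                      type = ifelse(pd[node_sel] == 0L, "isolated",
                                    ifelse(pd[node_sel] == 1L, "endpoint",
                                           "branch")))
  visited <- matrix(FALSE, nr, nc)   # consumed chain (degree-2) pixels
  edges <- list()

  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc & skel[cbind(pmax(1, pmin(nr, r)), pmax(1, pmin(nc, c)))]
  neighbors <- function(r, c) {
    rs <- r + NB8[, 1]; cs <- c + NB8[, 2]
    ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
    rs <- rs[ok]; cs <- cs[ok]
    on <- skel[cbind(rs, cs)]
    rs <- rs[on]; cs <- cs[on]
    # reduced adjacency: drop diagonal links short-circuited by an
    # orthogonal skeleton pixel
    diagonal <- rs != r & cs != c
    redundant <- diagonal & (at(rs, rep(c, length(rs))) | at(rep(r, length(rs)), cs))
    cbind(rs[!redundant], cs[!redundant])
  }
  walk_chain <- function(pr, pc, qr, qc) {
    # from node (pr,pc) into chain pixel (qr,qc); returns path matrix
    path_r <- c(pr, qr); path_c <- c(pc, qc)
    visited[qr, qc] <<- TRUE
    prev_r <- pr; prev_c <- pc; cur_r <- qr; cur_c <- qc
    repeat {
      nb <- neighbors(cur_r, cur_c)
      keep <- !(nb[, 1] == prev_r & nb[, 2] == prev_c)
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0) break            # dead end (shouldn't happen)
      nxt <- nb[1, ]                      # degree-2 pixel: unique next
      path_r <- c(path_r, nxt[1]); path_c <- c(path_c, nxt[2])
      if (is_node_m[nxt[1], nxt[2]]) break
      visited[nxt[1], nxt[2]] <<- TRUE
      prev_r <- cur_r; prev_c <- cur_c
      cur_r <- nxt[1]; cur_c <- nxt[2]
    }
    cbind(r = path_r, c = path_c)
  }

  node_idx <- which(node_sel)
  node_key <- px[node_sel, 1] + (px[node_sel, 2] - 1) * nr
  seen_nn <- character(0)   # dedup direct node-node edges
  for (k in seq_len(nrow(nodes))) {
    pr <- nodes$r[k]; pc <- nodes$c[k]
    nb <- neighbors(pr, pc)
    for (j in seq_len(nrow(nb))) {
      qr <- nb[j, 1]; qc <- nb[j, 2]
      if (is_node_m[qr, qc]) {
        a <- pr + (pc - 1) * nr; b <- qr + (qc - 1) * nr
        key <- paste(min(a, b), max(a, b))
        if (!key %in% seen_nn) {
          seen_nn <- c(seen_nn, key)
          edges[[length(edges) + 1]] <-
            list(path = cbind(r = c(pr, qr), c = c(pc, qc)), is_loop = FALSE)
        }
      } else if (!visited[qr, qc]) {
        edges[[length(edges) + 1]] <-
          list(path = walk_chain(pr, pc, qr, qc), is_loop = FALSE)
      }
    }
  }
  # pure cycles: unvisited degree-2 pixels
  remaining <- px[!node_sel & !visited[px], , drop = FALSE]
  while (nrow(remaining) > 0) {
    sr <- remaining[1, 1]; sc <- remaining[1, 2]  # lexicographic smallest
    visited[sr, sc] <- TRUE
    nb <- neighbors(sr, sc)
    ord <- order(nb[, 1], nb[, 2])
    q <- nb[ord[1], ]
    path_r <- c(sr, q[1]); path_c <- c(sc, q[2])
    visited[q[1], q[2]] <- TRUE
    prev_r <- sr; prev_c <- sc; cur_r <- q[1]; cur_c <- q[2]
    repeat {
      nb2 <- neighbors(cur_r, cur_c)
      keep <- !(nb2[, 1] == prev_r & nb2[, 2] == prev_c)
      nb2 <- nb2[keep, , drop = FALSE]
      if (nrow(nb2) == 0) break
      nxt <- nb2[1, ]
      if (nxt[1] == sr && nxt[2] == sc) break   # closed the cycle
      path_r <- c(path_r, nxt[1]); path_c <- c(path_c, nxt[2])
      visited[nxt[1], nxt[2]] <- TRUE
      prev_r <- cur_r; prev_c <- cur_c
      cur_r <- nxt[1]; cur_c <- nxt[2]
    }
    edges[[length(edges) + 1]] <-
      list(path = cbind(r = path_r, c = path_c), is_loop = TRUE)
    remaining <- remaining[!visited[remaining], , drop = FALSE]
    if (is.null(dim(remaining)))
      remaining <- matrix(remaining, ncol = 2)
  }
  structure(list(nodes = nodes, edges = edges, dim = c(nr, nc)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d endpoints, %d branch), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "endpoint"),
              sum(x$nodes$type == "branch"), length(x$edges)))
  invisible(x)
}

#' Extract ordered centerline tracks from a skeleton graph
#'
#' One track per graph edge of at least `min_length` points. When a label
#' map is supplied each track is attributed to an artery or vein by the
#' majority class of its pixels (junction pixels vote for neither; ties
#' fall to the first non-junction pixel); with a zone partition, tracks
#' are attributed to the zone holding the majority of their pixels (ties
#' to the first pixel's zone).
#'
#' @param graph A `skeleton_graph`.
#' @param min_length Minimum number of points (tracks shorter than the
#'   MDAC window cannot support tortuosity estimation).
#' @param map Optional `vessel_label_map` for class attribution.
#' @param zones Optional `zone_partition` for zone attribution.
#' @return List of `vessel_track`s: each a list with `points` (n x 2
#'   matrix, (r, c)), `n`, `vessel_class`, `zone`, `is_loop`.
#' @export
extract_tracks <- function(graph, min_length = 11, map = NULL, zones = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  out <- list()
  for (e in graph$edges) {
    n <- nrow(e$path)
    if (n < min_length) next
    cls <- NA_character_
    if (!is.null(map)) {
      lab <- map$classes[e$path]
      na_ <- sum(lab == 1L); nv <- sum(lab == 2L)
      if (na_ > nv) cls <- "artery"
      else if (nv > na_) cls <- "vein"
      else {
        first_nj <- lab[lab %in% c(1L, 2L)][1]
        cls <- if (is.na(first_nj) || first_nj == 1L) "artery" else "vein"
      }
    }
    zn <- NA_character_
    if (!is.null(zones)) {
      zc <- zones$zones[e$path]
      tab <- table(zc)
      best <- as.integer(names(tab)[tab == max(tab)])
      zn_code <- if (length(best) == 1) best else zc[1]
      zn <- names(ZONE_CODES)[match(zn_code, ZONE_CODES)]
    }
    out[[length(out) + 1]] <- structure(
      list(points = e$path, n = n, vessel_class = cls, zone = zn,
           is_loop = e$is_loop),
      class = "vessel_track")
  }
  out
}
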