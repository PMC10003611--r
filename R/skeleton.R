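# Skeletonization and skeleton-graph branch analysis. A skeleton component
# (8-connected) is one putative cell; a branch is a maximal run of slab
# pixels between two node pixels (endpoints or junctions), or an isolated
# cycle. Branch length is the Euclidean chain length of the pixel path
# (1 per orthogonal step, sqrt(2) per diagonal step) times the calibration.

#' Skeletonize a binary mask
#'
#' Iterative topology-preserving thinning to 1-pixel-wide curves. Border
#' pixels are removed in sequential directional passes, deleting only
#' 8-simple, non-endpoint pixels, so the result is a subset of the mask and
#' keeps its 8-connected component count; a final pass removes residual
#' 2x2 blocks. Pixel-exact agreement with any particular legacy thinner is
#' not claimed - the topological invariants are the contract.
#'
#' @param mask a [binary_mask()] (or 0/1 matrix).
#' @return A `skeleton_mask` (subclass of `binary_mask`).
#' @export
skeletonize <- function(mask) {
  px <- as_pixels(mask)
  m <- matrix(as.integer(px != 0), nrow(px), ncol(px))
  thin <- cpp_thin(m)
  structure(list(pixels = thin, um_per_px = um_per_px_of(mask)),
            class = c("skeleton_mask", "binary_mask"))
}

has_2x2_block <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 2 || w < 2) return(FALSE)
  a <- m[-h, -w] & m[-1, -w] & m[-h, -1] & m[-1, -1]
  any(a)
}

# 8-neighbour offsets, N NE E SE S SW W NW
NB8 <- cbind(di = c(-1, -1, 0, 1, 1, 1, 0, -1),
             dj = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Extract the branch table from a skeleton
#'
#' Labels 8-connected skeleton components (skeleton IDs numbered in
#' raster-scan order of each component's first pixel) and classifies every
#' skeleton pixel by its 8-neighbour count: endpoint (1), slab (2),
#' junction (>= 3). Adjacent junction pixels are merged into a single
#' junction node before path extraction, preventing spurious zero-length
#' branches. Each maximal slab path between two nodes, each direct
#' node-node adjacency, and each isolated cycle yields one branch record;
#' isolated single pixels (and components consisting solely of one merged
#' junction) yield one zero-length record so every component appears in
#' the table.
#'
#' A multi-way crossing cannot be represented by one pixel, so the
#' skeleton of a cell with five or six processes necessarily contains
#' short junction-to-junction connectors spanning the crossing zone,
#' whose extent is set by process thickness and soma size, not biology.
#' Junction nodes linked by a slab path of at most `junction_merge_px`
#' pixels are therefore treated as one node region: the connector yields
#' no branch record. `junction_merge_px = 0` reproduces the raw graph.
#' Endpoint-terminated branches are never dropped (no spur pruning).
#'
#' @param skel a `skeleton_mask` from [skeletonize()].
#' @param junction_merge_px junction-junction connectors with pixel path
#'   length at or below this are absorbed into the node region. Default
#'   8 px, the expected soma diameter plus process thickness.
#' @return `data.frame` with columns `skeleton_id` (integer) and
#'   `branch_length_um` (numeric), the analog of the "Branch information"
#'   table.
#' @export
build_branch_table <- function(skel, junction_merge_px = 8) {
  px <- as_pixels(skel)
  um <- um_per_px_of(skel)
  h <- nrow(px); w <- ncol(px)
  if (sum(px) == 0)
    return(data.frame(skeleton_id = integer(0), branch_length_um = numeric(0)))
  if (has_2x2_block(px == 1))
    stop_input("input is not a thin skeleton (contains a 2x2 block)")
  lab <- cpp_label8(px)
  nbr <- cpp_neighbor_count8(px)
  isfg <- px == 1L

  jmask <- matrix(as.integer(isfg & nbr >= 3L), h, w)
  jl <- cpp_label8(jmask)
  njunc <- max(jl)
  nodeid <- matrix(0L, h, w)
  nodeid[jmask == 1L] <- jl[jmask == 1L]
  is_node <- isfg & (nbr == 1L | nbr >= 3L)
  ep_lin <- which(isfg & nbr == 1L)
  nodeid[ep_lin] <- njunc + seq_along(ep_lin)

  raster_idx <- function(i, j) (i - 1L) * w + j
  fg_at <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && isfg[i, j]
  fg_neighbors <- function(i, j) {
    out <- matrix(0L, 0, 2)
    for (k in 1:8) {
      ii <- i + NB8[k, 1]; jj <- j + NB8[k, 2]
      if (fg_at(ii, jj)) out <- rbind(out, c(ii, jj))
    }
    out
  }
  step_len <- function(a, b)
    if (a[1] != b[1] && a[2] != b[2]) sqrt(2) else 1

  visited <- matrix(FALSE, h, w)
  res_id <- integer(0); res_len <- numeric(0); res_jj <- logical(0)
  add <- function(comp, len_px, jj = FALSE) {
    res_id[length(res_id) + 1L] <<- comp
    res_len[length(res_len) + 1L] <<- len_px * um
    res_jj[length(res_jj) + 1L] <<- jj && len_px <= junction_merge_px
  }

  # node pixels in raster-scan order
  node_lin <- which(is_node)
  ni <- ((node_lin - 1L) %% h) + 1L
  nj <- ((node_lin - 1L) %/% h) + 1L
  ord <- order(raster_idx(ni, nj))
  ni <- ni[ord]; nj <- nj[ord]

  for (k in seq_along(ni)) {
    i <- ni[k]; j <- nj[k]
    p <- c(i, j)
    nbs <- fg_neighbors(i, j)
    for (q in seq_len(nrow(nbs))) {
      qq <- nbs[q, ]
      if (is_node[qq[1], qq[2]]) {
        # direct node-node branch; record once, from the smaller raster index
        if (nodeid[qq[1], qq[2]] != nodeid[i, j] &&
            raster_idx(i, j) < raster_idx(qq[1], qq[2]))
          add(lab[i, j], step_len(p, qq),
              jj = nbr[i, j] >= 3L && nbr[qq[1], qq[2]] >= 3L)
      } else if (!visited[qq[1], qq[2]]) {
        # walk the slab path until the next node
        len <- step_len(p, qq)
        visited[qq[1], qq[2]] <- TRUE
        prev <- p; cur <- qq
        repeat {
          cn <- fg_neighbors(cur[1], cur[2])
          nxt <- NULL
          for (z in seq_len(nrow(cn)))
            if (!(cn[z, 1] == prev[1] && cn[z, 2] == prev[2])) nxt <- cn[z, ]
          len <- len + step_len(cur, nxt)
          if (is_node[nxt[1], nxt[2]]) break
          visited[nxt[1], nxt[2]] <- TRUE
          prev <- cur; cur <- nxt
        }
        add(lab[i, j], len,
            jj = nbr[i, j] >= 3L && nbr[nxt[1], nxt[2]] >= 3L)
      }
    }
    if (nbr[i, j] == 0L) add(lab[i, j], 0)  # isolated pixel
  }

  # pure cycles: slab pixels never reached from any node
  slab_lin <- which(isfg & nbr == 2L & !visited)
  if (length(slab_lin) > 0) {
    si <- ((slab_lin - 1L) %% h) + 1L
    sj <- ((slab_lin - 1L) %/% h) + 1L
    sord <- order(raster_idx(si, sj))
    for (k in sord) {
      i <- si[k]; j <- sj[k]
      if (visited[i, j]) next
      start <- c(i, j)
      visited[i, j] <- TRUE
      nbs <- fg_neighbors(i, j)
      prev <- start; cur <- nbs[1, ]
      len <- step_len(start, cur)
      while (!(cur[1] == start[1] && cur[2] == start[2])) {
        visited[cur[1], cur[2]] <- TRUE
        cn <- fg_neighbors(cur[1], cur[2])
        nxt <- NULL
        for (z in seq_len(nrow(cn)))
          if (!(cn[z, 1] == prev[1] && cn[z, 2] == prev[2])) nxt <- cn[z, ]
        len <- len + step_len(cur, nxt)
        prev <- cur; cur <- nxt
      }
      add(lab[i, j], len)
    }
  }

  # drop junction-junction connectors inside a node region
  if (any(res_jj)) {
    res_id <- res_id[!res_jj]
    res_len <- res_len[!res_jj]
  }

  # components with no branch at all (e.g. one merged junction): 0-length
  ncomp <- max(lab)
  missing <- setdiff(seq_len(ncomp), unique(res_id))
  for (comp in missing) add(comp, 0)

  out <- data.frame(skeleton_id = res_id, branch_length_um = res_len)
  out <- out[order(out$skeleton_id, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
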