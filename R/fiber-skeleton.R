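# Shift a logical matrix by (dr, dc) with FALSE padding.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbourhood of every pixel, Zhang-Suen order P2..P9 (N, NE, E, SE, S,
# SW, W, NW).
neighbor_stack <- function(m) {
  list(shift_mat(m, 1, 0), shift_mat(m, 1, -1), shift_mat(m, 0, -1),
       shift_mat(m, -1, -1), shift_mat(m, -1, 0), shift_mat(m, -1, 1),
       shift_mat(m, 0, 1), shift_mat(m, 1, 1))
}

neighbor_count <- function(m) Reduce(`+`, neighbor_stack(m))

#' Otsu binarisation of a grayscale fiber image
#'
#' Threshold maximising between-class variance on a 256-bin histogram.
#' Boolean input passes through unchanged; a constant image is an error.
#'
#' @param img Numeric or logical matrix (grayscale fluorescence field).
#' @param method Currently `"otsu"`.
#' @return Logical matrix (foreground = fibers) with the chosen threshold in
#'   attribute `threshold` (on the original intensity scale).
#' @export
binarize <- function(img, method = "otsu") {
  if (is.logical(img)) return(img)
  stopifnot(is.matrix(img), is.numeric(img), method == "otsu")
  rng <- range(img)
  if (diff(rng) == 0) abort("constant image: cannot threshold")
  x <- (img - rng[1]) / diff(rng)
  counts <- tabulate(pmin(floor(x * 256) + 1L, 256L), 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  thr <- rng[1] + (k / 256) * diff(rng)
  out <- img > thr
  attr(out, "threshold") <- thr
  out
}

# Zhang-Suen thinning to a 1-px, 8-connected skeleton (topology preserving).
zhang_suen <- function(m) {
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- neighbor_stack(m)
      B <- Reduce(`+`, nb)
      seqs <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(k) !seqs[[k]] & seqs[[k + 1]]))
      p2 <- nb[[1]]; p4 <- nb[[3]]; p6 <- nb[[5]]; p8 <- nb[[7]]
      if (phase == 1) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Cluster pixel coordinates (n x 2 matrix) into 8-connected components;
# returns a list of coordinate matrices.
cluster_pixels <- function(coords, dim) {
  if (is.null(nrow(coords))) coords <- matrix(coords, ncol = 2)
  n <- nrow(coords)
  if (n == 0L) return(list())
  key <- (coords[, 1] - 1) + (coords[, 2] - 1) * dim[1]
  lookup <- new.env(hash = TRUE, size = n)
  for (k in seq_len(n)) assign(as.character(key[k]), k, envir = lookup)
  comp <- integer(n)
  ncomp <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (o in seq_len(8)) {
        nk <- (coords[cur, 1] - 1 + offs$dr[o]) + (coords[cur, 2] - 1 + offs$dc[o]) * dim[1]
        hit <- mget(as.character(nk), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && comp[hit] == 0L) {
          comp[hit] <- ncomp
          queue <- c(queue, hit)
        }
      }
    }
  }
  split.data.frame(coords, comp)
}

#' Skeleton metrics of a binary fiber image
#'
#' Thins the foreground to a one-pixel skeleton (Zhang-Suen, topology
#' preserving) and measures: total fiber length (chain-code convention — 1
#' per axis-aligned inter-pixel step, sqrt(2) per diagonal, diagonals
#' shortcutting an existing axis step not double-counted — times the pixel
#' size), the number of branch points (skeleton pixels with 3+ skeleton
#' neighbours, 8-connected clusters merged to a single junction), and the
#' junction/endpoint graph.
#'
#' @param img Logical matrix (or grayscale, which is [binarize()]d first).
#' @param pixel_size_um Pixel edge length in micrometres (default 1).
#' @return A list of class `skeleton_metrics`: `total_length_um`,
#'   `n_branch_points`, `graph` (a [skeleton_graph()]), and `skeleton`
#'   (logical matrix).
#' @examples
#' img <- matrix(FALSE, 20, 20); img[10, 3:18] <- TRUE
#' skeleton_metrics(img)$total_length_um  # 15
#' @export
skeleton_metrics <- function(img, pixel_size_um = 1) {
  if (!is.logical(img)) img <- binarize(img)
  if (!any(img)) abort("empty foreground")
  assert_scalar_number(pixel_size_um, "pixel_size_um", lo = 1e-12)
  sk <- zhang_suen(img)
  # length: count adjacency edges once; drop diagonals that shortcut an
  # axis-aligned two-step path through a common 4-neighbour
  e_count <- shift_mat(sk, 0, -1)          # east neighbour exists
  s_count <- shift_mat(sk, -1, 0)          # south neighbour
  se <- shift_mat(sk, -1, -1) & !(shift_mat(sk, -1, 0) | shift_mat(sk, 0, -1))
  sw <- shift_mat(sk, -1, 1) & !(shift_mat(sk, -1, 0) | shift_mat(sk, 0, 1))
  n_orth <- sum(sk & e_count) + sum(sk & s_count)
  n_diag <- sum(sk & se) + sum(sk & sw)
  total_length <- (n_orth + sqrt(2) * n_diag) * pixel_size_um
  graph <- skeleton_graph(sk, pixel_size_um)
  structure(list(total_length_um = total_length,
                 n_branch_points = sum(graph$nodes$type == "junction"),
                 graph = graph, skeleton = sk),
            class = "skeleton_metrics")
}

#' Junction/endpoint graph of a skeleton
#'
#' Nodes are skeleton endpoints (exactly one skeleton neighbour) and
#' junctions (8-connected clusters of pixels with 3+ neighbours, merged to a
#' single node); edges are the skeleton paths between them with chain-code
#' path length in micrometres.  Isolated single pixels are dropped; isolated
#' closed loops contribute no nodes.
#'
#' @param sk Logical skeleton matrix (already thinned).
#' @param pixel_size_um Pixel size in micrometres.
#' @return A list of class `skeleton_graph`: `nodes` (tibble `node`, `type`,
#'   `row`, `col`, `degree`) and `edges` (tibble `from`, `to`, `length_um`).
#' @export
skeleton_graph <- function(sk, pixel_size_um = 1) {
  nc <- neighbor_count(sk)
  nb_on <- ifelse(sk, nc, 0L)
  end_coords <- which(sk & nb_on == 1L, arr.ind = TRUE)
  branch_coords <- which(sk & nb_on >= 3L, arr.ind = TRUE)
  clusters <- cluster_pixels(branch_coords, dim(sk))
  # node id per skeleton pixel: 0 = path pixel
  node_of <- matrix(0L, nrow(sk), ncol(sk))
  nodes <- list()
  nid <- 0L
  for (k in seq_len(nrow(end_coords))) {
    nid <- nid + 1L
    node_of[end_coords[k, 1], end_coords[k, 2]] <- nid
    nodes[[nid]] <- tibble(node = nid, type = "endpoint",
                           row = end_coords[k, 1], col = end_coords[k, 2])
  }
  for (cl in clusters) {
    nid <- nid + 1L
    for (k in seq_len(nrow(cl))) node_of[cl[k, 1], cl[k, 2]] <- nid
    nodes[[nid]] <- tibble(node = nid, type = "junction",
                           row = round(mean(cl[, 1])), col = round(mean(cl[, 2])))
  }
  nodes <- if (length(nodes)) dplyr::bind_rows(nodes) else
    tibble(node = integer(), type = character(), row = integer(), col = integer())
  edges <- trace_edges(sk, node_of, pixel_size_um)
  deg <- integer(nrow(nodes))
  if (nrow(edges)) {
    tab <- table(factor(c(edges$from, edges$to), levels = nodes$node))
    deg <- as.integer(tab)
  }
  nodes$degree <- deg
  structure(list(nodes = nodes, edges = edges), class = "skeleton_graph")
}

step_len <- function(dr, dc) ifelse(abs(dr) + abs(dc) == 2, sqrt(2), 1)

trace_edges <- function(sk, node_of, pixel_size_um) {
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nr <- nrow(sk); ncm <- ncol(sk)
  sk_at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= ncm && sk[r, c]
  node_pix <- which(node_of > 0L, arr.ind = TRUE)
  used <- matrix(FALSE, nr, ncm)   # path pixels already consumed
  out <- list()
  add_edge <- function(a, b, len) {
    out[[length(out) + 1L]] <<- tibble(from = min(a, b), to = max(a, b),
                                       length_um = len * pixel_size_um)
  }
  for (k in seq_len(nrow(node_pix))) {
    r0 <- node_pix[k, 1]; c0 <- node_pix[k, 2]
    id0 <- node_of[r0, c0]
    for (o in seq_len(8)) {
      r <- r0 + offs[o, 1]; c <- c0 + offs[o, 2]
      if (!sk_at(r, c)) next
      if (node_of[r, c] > 0L) {
        # direct node-to-node adjacency: count once from the lower pixel index
        if (node_of[r, c] != id0 &&
            (r0 + (c0 - 1) * nr) < (r + (c - 1) * nr)) {
          add_edge(id0, node_of[r, c], step_len(offs[o, 1], offs[o, 2]))
        }
        next
      }
      if (used[r, c]) next
      # walk the path until the next node
      len <- step_len(offs[o, 1], offs[o, 2])
      pr <- r0; pc <- c0
      repeat {
        used[r, c] <- TRUE
        nxt <- NULL
        for (oo in seq_len(8)) {
          rr <- r + offs[oo, 1]; cc <- c + offs[oo, 2]
          if (!sk_at(rr, cc) || (rr == pr && cc == pc)) next
          if (node_of[rr, cc] > 0L) {
            add_edge(id0, node_of[rr, cc], len + step_len(offs[oo, 1], offs[oo, 2]))
            nxt <- "done"
            break
          }
          if (!used[rr, cc]) {
            nxt <- c(rr, cc)
            break
          }
        }
        if (is.null(nxt) || identical(nxt, "done")) break
        len <- len + step_len(nxt[1] - r, nxt[2] - c)
        pr <- r; pc <- c
        r <- nxt[1]; c <- nxt[2]
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(from = integer(), to = integer(), length_um = numeric())
}

#' Node-degree density of a skeleton graph
#'
#' Fraction of graph nodes (junctions and endpoints) at each degree; sums
#' to 1.
#'
#' @param graph A [skeleton_graph()] (or a `skeleton_metrics` result).
#' @return A tibble with columns `degree` and `density`.
#' @export
node_degree_density <- function(graph) {
  if (inherits(graph, "skeleton_metrics")) graph <- graph$graph
  stopifnot(inherits(graph, "skeleton_graph"))
  if (nrow(graph$nodes) == 0L) abort("graph has no nodes")
  tab <- table(graph$nodes$degree)
  tibble(degree = as.integer(names(tab)),
         density = as.numeric(tab) / nrow(graph$nodes))
}

#' Read a fiber image from PNG or TIFF
#'
#' @param path Image path; multi-channel images are averaged to grayscale.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_fiber_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("package '%s' is required to read .%s files", pkg, ext))
    }
  }
  img <- switch(ext,
    png = { need("png"); png::readPNG(path) },
    tif = ,
    tiff = { need("tiff"); tiff::readTIFF(path) },
    abort("unsupported image format (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}
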