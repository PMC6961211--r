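# Independent brute-force oracles, deliberately implemented with different
# machinery than the package (level-set connected components via igraph and
# direct per-pixel sorts) so they can arbitrate the fast implementations.

shift_mat <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[oky, okx] <- m[ys[oky], xs[okx], drop = FALSE]
  out
}

neigh8 <- local({
  g <- expand.grid(dy = -1:1, dx = -1:1)
  g[!(g$dy == 0 & g$dx == 0), ]
})

# 8-connected component labels of a logical mask (NA outside the mask)
cc_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(NA_integer_, nr, nc)
  if (length(idx) == 0) return(out)
  id <- matrix(NA_integer_, nr, nc)
  id[idx] <- seq_along(idx)
  half <- neigh8[neigh8$dy > 0 | (neigh8$dy == 0 & neigh8$dx > 0), ]
  edges <- integer(0)
  for (k in seq_len(nrow(half))) {
    sh <- shift_mat(id, half$dy[k], half$dx[k], NA_integer_)
    both <- !is.na(id) & !is.na(sh)
    if (any(both)) edges <- c(edges, rbind(id[both], sh[both]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  out[idx] <- igraph::components(g)$membership
  out
}

# Brute-force topographic-prominence maxima. For every equal-valued plateau
# with no strictly higher neighbour, the level set {img >= v - tol} is
# labelled; the plateau is accepted iff its level-set component contains no
# pixel above v, and accepted equal-valued plateaus sharing a component
# merge into one peak (representative: lexicographically smallest (y, x)
# plateau member of the group). Returns 0-based (x, y) sorted by (y, x).
oracle_find_maxima <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  empty <- data.frame(x = integer(0), y = integer(0))
  if (max(img) == min(img)) return(empty)
  nmax <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(neigh8)))
    nmax <- pmax(nmax, shift_mat(img, neigh8$dy[k], neigh8$dx[k], -Inf))
  plab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  for (v in unique(as.vector(img))) {
    lv <- cc_label(img == v)
    for (id in unique(lv[!is.na(lv)])) {
      nxt <- nxt + 1L
      plab[!is.na(lv) & lv == id] <- nxt
    }
  }
  cand <- integer(0)
  for (p in seq_len(nxt)) {
    mem <- plab == p
    if (max(nmax[mem]) <= img[which(mem)[1]]) cand <- c(cand, p)
  }
  region_cache <- list()
  groups <- list()
  for (p in cand) {
    mem_idx <- which(plab == p)
    v <- img[mem_idx[1]]
    key_v <- format(v, digits = 17)
    if (is.null(region_cache[[key_v]]))
      region_cache[[key_v]] <- cc_label(img >= v - tol)
    reg <- region_cache[[key_v]]
    rid <- reg[mem_idx[1]]
    if (max(img[!is.na(reg) & reg == rid]) > v) next
    key <- paste(key_v, rid)
    groups[[key]] <- c(groups[[key]], mem_idx)
  }
  if (length(groups) == 0) return(empty)
  reps <- vapply(groups, function(members) {
    y <- (members - 1) %% nr
    x <- (members - 1) %/% nr
    members[order(y, x)[1]]
  }, 0L)
  y <- (reps - 1) %% nr
  x <- (reps - 1) %/% nr
  o <- order(y, x)
  data.frame(x = as.integer(x[o]), y = as.integer(y[o]))
}

# direct per-pixel sort median with the circular kernel and edge replication
oracle_median_filter <- function(img, radius) {
  r <- floor(radius) + 1
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2 + 1, ]
  nr <- nrow(img); nc <- ncol(img)
  out <- img + 0.0
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    yy <- pmin(pmax(y + offs$dy, 1), nr)
    xx <- pmin(pmax(x + offs$dx, 1), nc)
    out[y, x] <- stats::median(img[cbind(yy, xx)])
  }
  out
}

# random integer raster for oracle-equivalence sweeps
random_raster <- function(seed, max_side = 32, vmax = 20) {
  set.seed(seed)
  nr <- sample(4:max_side, 1)
  nc <- sample(4:max_side, 1)
  matrix(sample(0:vmax, nr * nc, replace = TRUE), nr, nc)
}

expect_same_peaks <- function(img, tol) {
  got <- find_maxima(img, tol)[, c("x", "y")]
  want <- oracle_find_maxima(img, tol)
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
}

# hand-constructed ridge / plateau rasters exercising merge and saddle logic
handmade_maxima_cases <- function() {
  cases <- list()
  add <- function(m, tol) cases[[length(cases) + 1]] <<- list(img = m, tol = tol)
  flat <- matrix(3, 6, 6)
  add(flat, 0.5)
  spike <- matrix(0, 7, 7); spike[4, 4] <- 10
  add(spike, 0.5)
  ridge <- matrix(0, 5, 9); ridge[3, 3] <- 10; ridge[3, 7] <- 10
  ridge[3, 4:6] <- 9.8
  add(ridge, 0.5); add(ridge, 0.1)
  twin <- matrix(0, 5, 9); twin[3, 3] <- 10; twin[3, 7] <- 9
  twin[3, 4:6] <- 8.6
  add(twin, 0.5); add(twin, 1.5)
  plate <- matrix(1, 8, 8); plate[3:5, 3:5] <- 7
  add(plate, 0.5)
  border <- matrix(2, 6, 6); border[1, 1] <- 9; border[6, 6] <- 9
  add(border, 0.5); add(border, 8)
  steps <- matrix(rep(1:8, each = 8), 8, 8)        # monotone staircase
  add(steps, 0.5)
  donut <- matrix(0, 9, 9); donut[3:7, 3:7] <- 5; donut[5, 5] <- 2
  add(donut, 0.5)
  saddle <- matrix(0, 7, 13)
  saddle[4, 3] <- 10; saddle[4, 11] <- 12; saddle[4, 4:10] <- 9.7
  add(saddle, 0.2); add(saddle, 0.5)
  diag_ridge <- matrix(0, 8, 8); diag(diag_ridge) <- 6
  diag_ridge[3, 3] <- 8; diag_ridge[6, 6] <- 8
  add(diag_ridge, 1.5); add(diag_ridge, 2.5)
  plateau_pair <- matrix(0, 6, 12)
  plateau_pair[3:4, 2:4] <- 5; plateau_pair[3:4, 8:10] <- 5
  plateau_pair[3, 5:7] <- 4.8
  add(plateau_pair, 0.1); add(plateau_pair, 0.5)
  tiny <- matrix(c(1, 2, 2, 1), 2, 2)
  add(tiny, 0.5); add(tiny, 1.5)
  neg <- matrix(-5, 5, 5); neg[2, 2] <- -1; neg[4, 4] <- -1.5
  add(neg, 1); add(neg, 4)
  cases
}
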