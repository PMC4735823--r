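# Independent oracles, deliberately written without touching the package's
# compiled paths: plain-R brute force over every edge / pixel / pair.

# full Hamiltonian by explicit edge enumeration (R implementation)
oracle_total_energy <- function(sigma, ep, polarity = NULL) {
  K <- max(0L, sigma)
  if (is.null(polarity)) polarity <- matrix(0, K, 2)
  Jof <- function(a, b) {
    if (a == b) return(0)
    cls <- function(s) if (s >= 1) "cell" else if (s == 0) "fluid" else "fibre"
    ep$J[cls(a), cls(b)]
  }
  nx <- nrow(sigma); ny <- ncol(sigma)
  E <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (i < nx) E <- E + Jof(sigma[i, j], sigma[i + 1, j])
    if (j < ny) E <- E + Jof(sigma[i, j], sigma[i, j + 1])
  }
  for (k in seq_len(K)) {
    px <- which(sigma == k, arr.ind = TRUE)
    a <- nrow(px)
    perim <- 0
    if (a > 0) {
      for (q in seq_len(a)) {
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- px[q, 1] + d[1]; jj <- px[q, 2] + d[2]
          if (ii < 1 || jj < 1 || ii > nx || jj > ny) next
          if (sigma[ii, jj] != k) perim <- perim + 1
        }
      }
    }
    E <- E + ep$lambda_a * (a - ep$a0)^2 + ep$lambda_p * (perim - ep$p0)^2
    if (a > 0) {
      cx <- mean(px[, 1] - 0.5); cy <- mean(px[, 2] - 0.5)
      E <- E - ep$mu0 * (polarity[k, 1] * cx + polarity[k, 2] * cy)
    }
  }
  E
}

# brute-force cluster partition by pairwise pixel-contact search
oracle_clusters <- function(sigma) {
  ids <- sort(unique(sigma[sigma >= 1L]))
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  pxs <- lapply(ids, function(k) which(sigma == k, arr.ind = TRUE))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    pa <- pxs[[a]]; pb <- pxs[[b]]
    touch <- FALSE
    for (q in seq_len(nrow(pa))) {
      d <- abs(pb[, 1] - pa[q, 1]) + abs(pb[, 2] - pa[q, 2])
      if (any(d == 1)) { touch <- TRUE; break }
    }
    adj[a, b] <- adj[b, a] <- touch
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  list(n = cur, sizes = sort(tabulate(comp), decreasing = TRUE))
}

# random toy lattice with contiguous cell ids (fibre sprinkled in)
random_toy_sigma <- function(n = 30, p_fibre = 0.15, n_cells = 3) {
  sg <- matrix(sample(c(rep(0L, 3), seq_len(n_cells), -1L), n * n,
                      replace = TRUE,
                      prob = c(rep((1 - p_fibre) / (3 + n_cells), 3 + n_cells),
                               p_fibre)),
               n, n)
  ids <- sort(unique(sg[sg >= 1L]))
  if (length(ids) > 0) sg[sg >= 1L] <- match(sg[sg >= 1L], ids)
  sg
}

# small lattice + state for engine tests
toy_state <- function(sigma, ep = energy_params(), mp = mmp_params()) {
  initialize_state(sim_lattice(sigma), ep, mp)
}
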