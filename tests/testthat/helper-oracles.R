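# Independent oracles used across the suite: brute-force enumerations and a
# direct numerical optimizer, deliberately written without reusing the
# package's dynamic programs.

# random ultrametric dated tree (coalescent)
randomDatedTree <- function(ntips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  datedTree(ape::rcoal(ntips, tip.label = paste0("t", seq_len(ntips))))
}

# exhaustive minimum parsimony cost over all ancestral-state assignments
# (missing tips are enumerated too)
bruteSankoff <- function(pattern, dtree, gain, loss) {
  tr <- dtree@tree
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  states <- rep(NA_integer_, nn)
  v <- pattern[tr$tip.label]
  fixed <- which(v != 2L)
  states[fixed] <- v[fixed]
  free <- c(which(v == 2L), (ntip + 1L):nn)
  trans_cost <- function(a, b) if (a == b) 0 else if (a == 0L) gain else loss
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(free)))
  for (g in seq_len(nrow(grid))) {
    states[free] <- as.integer(grid[g, ])
    cost <- 0
    for (e in seq_len(nrow(tr$edge)))
      cost <- cost + trans_cost(states[tr$edge[e, 1L]], states[tr$edge[e, 2L]])
    if (cost < best) best <- cost
  }
  best
}

# brute-force likelihood: sum over all internal (and missing-tip) states of
# pi(root) * prod over edges of the 2-state transition probability
bruteLogLik <- function(pattern, dtree, gain, loss, pi1) {
  tr <- dtree@tree
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  v <- pattern[tr$tip.label]
  free <- c(which(v == 2L), (ntip + 1L):nn)
  states <- rep(NA_integer_, nn)
  fixed <- which(v != 2L)
  states[fixed] <- v[fixed]
  ptrans <- function(a, b, t) {
    r <- gain + loss
    if (r == 0 || t == 0) return(as.numeric(a == b))
    e <- exp(-r * t)
    if (a == 0L && b == 0L) (loss + gain * e) / r
    else if (a == 0L) gain * (1 - e) / r
    else if (b == 0L) loss * (1 - e) / r
    else (gain + loss * e) / r
  }
  total <- 0
  grid <- expand.grid(rep(list(0:1), length(free)))
  for (g in seq_len(nrow(grid))) {
    states[free] <- as.integer(grid[g, ])
    pr <- if (states[ntip + 1L] == 1L) pi1 else 1 - pi1
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * ptrans(states[tr$edge[e, 1L]], states[tr$edge[e, 2L]],
                        tr$edge.length[e])
    total <- total + pr
  }
  log(total)
}

# direct numerical maximisation of the observed-data log-likelihood over
# (omega0, omega, theta11), independent of the EM path
directNoisyOpt <- function(x, z, nStarts = 12L, seed = 99L) {
  set.seed(seed)
  X <- standardizeFeatures(x)$x
  d <- ncol(X)
  nll <- function(par)
    -observedLogLik(X, z, par[seq_len(d) + 1L], par[1L], stats::plogis(par[d + 2L]))
  g <- suppressWarnings(stats::glm.fit(cbind(1, X), z,
                                       family = stats::binomial())$coefficients)
  g[!is.finite(g)] <- 0
  starts <- c(lapply(stats::qlogis(c(0.15, 0.5, 0.85, 0.98)),
                     function(t) c(-g[1], g[-1], t)),
              lapply(seq_len(nStarts), function(s)
                c(stats::rnorm(d + 1L, 0, 0.5), stats::rnorm(1))))
  best <- Inf
  for (p0 in starts) {
    o <- tryCatch(stats::optim(unname(p0), nll, method = "BFGS",
                               control = list(maxit = 3000, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  -best
}

# hand-made ternary column container (bypasses encodeTernary)
makeCols <- function(values, set_id = "s1", position = NULL,
                     cds_length = 1000L, tags = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values)
  if (is.null(position)) position <- seq_len(n) * 10L
  list(values = values,
       info = data.frame(set_id = rep_len(set_id, n), column = seq_len(n),
                         position = as.integer(position),
                         cds_length = rep_len(as.integer(cds_length), n),
                         tags = rep_len(tags, n), stringsAsFactors = FALSE))
}
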