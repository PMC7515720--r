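#' Enumerate admissible ribosome configurations on a small lattice
#'
#' A configuration is the ordered set of occupied A-site codons; any two
#' A-sites must be at least `ell` codons apart and all lie in `2..L`.  The
#' empty lattice is included.  Intended for lattices small enough that the
#' stationary master equation can be solved exactly.
#'
#' @param L transcript length in codons (including START and STOP).
#' @param ell ribosome footprint in codons.
#' @param cap maximum admissible state-space size (default `2e5`); exceeding
#'   it is an error so the caller can fall back to simulation.
#' @return List of integer vectors (ascending A-site positions); the first
#'   element is `integer(0)`, the empty lattice.
#' @export
enumerate_configurations <- function(L, ell, cap = 2e5) {
  stopifnot(L >= ell + 1)
  n_conf <- count_configurations(L, ell)
  if (n_conf > cap)
    stop("state space too large: ", n_conf, " configurations exceed cap ", cap)
  out <- vector("list", n_conf)
  out[[1]] <- integer(0)
  idx <- 1L
  # depth-first: extend each prefix by every admissible next A-site
  stack <- list(integer(0))
  while (length(stack)) {
    pre <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- if (length(pre)) pre[length(pre)] + ell else 2L
    if (lo > L) next
    for (j in seq.int(lo, L)) {
      conf <- c(pre, j)
      idx <- idx + 1L
      out[[idx]] <- conf
      stack[[length(stack) + 1L]] <- conf
    }
  }
  out
}

#' Count admissible configurations without enumerating them
#'
#' @inheritParams enumerate_configurations
#' @return Number of arrangements of A-sites on codons `2..L` with pairwise
#'   spacing at least `ell`, including the empty lattice.
#' @export
count_configurations <- function(L, ell) {
  # g[i]: number of admissible arrangements on sites i..L (empty included);
  # either site i is empty (g[i+1]) or holds an A-site (g[i+ell])
  g <- rep(1, L + ell)              # g[i] = 1 for i > L
  for (i in L:2) g[i] <- g[i + 1] + g[i + ell]
  g[2]
}

# transitions enabled from one configuration (shared by solver and tests):
# initiation if codons 2..ell+1 hold no A-site; hop i -> i+1 if the next
# A-site is at i+ell+1 or beyond; termination from L unconditionally
.config_moves <- function(conf, L, ell, alpha, k) {
  # k is indexed so k[i] is the rate of codon i (k[1] = NA)
  moves <- list()
  if (length(conf) == 0L || conf[1] >= ell + 2L)
    moves[[length(moves) + 1L]] <- list(to = c(2L, conf), rate = alpha)
  m <- length(conf)
  for (r in seq_len(m)) {
    i <- conf[r]
    if (i == L) {
      moves[[length(moves) + 1L]] <- list(to = conf[-r], rate = k[L])
    } else if (r == m || conf[r + 1] >= i + ell + 1L) {
      nxt <- conf
      nxt[r] <- i + 1L
      moves[[length(moves) + 1L]] <- list(to = nxt, rate = k[i])
    }
  }
  moves
}

#' Exact stationary state of the translation exclusion process
#'
#' Assembles the sparse generator of the master equation over all admissible
#' configurations and solves the stationary linear system directly.  Only
#' feasible for small lattices (the state space grows combinatorially); its
#' role is to be the correctness oracle for the simulator and the analytic
#' approximations.
#'
#' @param rates a [gene_rates()] (absolute rates) or [kappa_profile()]
#'   (relative rates; solved with `alpha = 1`, which leaves densities
#'   unchanged).
#' @param cap maximum state-space size, see [enumerate_configurations()].
#' @return A [density_profile()] with `source = "EXACT"`, plus attributes:
#'   `J` (protein production rate), `J_bond` (per-transition currents,
#'   codons `2..L`), `J_init` (initiation current), `clearance` (per-codon
#'   conditional probability that codons `i+1..i+ell` hold no A-site given
#'   an A-site at `i`), and `pi` (the stationary probabilities).
#' @export
exact_stationary <- function(rates, cap = 2e5) {
  p <- .as_alpha_k(rates)
  L <- p$L; ell <- p$ell; alpha <- p$alpha
  k <- c(NA_real_, p$k)             # k[i] for codon i
  confs <- enumerate_configurations(L, ell, cap = cap)
  n <- length(confs)
  keys <- vapply(confs, function(cf) paste(c("c", cf), collapse = ","), "")
  index <- new.env(hash = TRUE, size = n)
  for (c_i in seq_len(n)) assign(keys[c_i], c_i, envir = index)

  from_l <- vector("list", n); to_l <- vector("list", n)
  rate_l <- vector("list", n)
  outrate <- numeric(n)
  for (c_i in seq_len(n)) {
    mv <- .config_moves(confs[[c_i]], L, ell, alpha, k)
    to_l[[c_i]] <- vapply(mv, function(m)
      get(paste(c("c", m$to), collapse = ","), envir = index), integer(1))
    rate_l[[c_i]] <- vapply(mv, `[[`, numeric(1), "rate")
    from_l[[c_i]] <- rep.int(c_i, length(mv))
    outrate[c_i] <- sum(rate_l[[c_i]])
  }
  from <- unlist(from_l); to <- unlist(to_l); rate <- unlist(rate_l)

  # stationary pi solves pi Q = 0; build A = t(Q) with the n-th balance
  # equation replaced by the normalization sum(pi) = 1
  ai <- c(to, seq_len(n))                  # A[to, from] += rate; A[i,i] -= out
  aj <- c(from, seq_len(n))
  ax <- c(rate, -outrate)
  sel <- ai != n
  A <- Matrix::sparseMatrix(i = c(ai[sel], rep(n, n)),
                            j = c(aj[sel], seq_len(n)),
                            x = c(ax[sel], rep(1, n)),
                            dims = c(n, n))
  b <- c(numeric(n - 1L), 1)
  pi_vec <- as.numeric(Matrix::solve(A, b))
  if (any(!is.finite(pi_vec)))
    stop("stationary solve failed (singular generator)")
  pi_vec[pi_vec < 0 & pi_vec > -1e-14] <- 0
  pi_vec <- pi_vec / sum(pi_vec)

  rho <- numeric(L - 1L)            # codons 2..L
  clear_num <- numeric(L - 1L)
  J_bond <- numeric(L - 1L)
  J_init <- 0
  for (c_i in seq_len(n)) {
    conf <- confs[[c_i]]
    w <- pi_vec[c_i]
    if (length(conf) == 0L || conf[1] >= ell + 2L) J_init <- J_init + alpha * w
    m <- length(conf)
    for (r in seq_len(m)) {
      i <- conf[r]
      rho[i - 1L] <- rho[i - 1L] + w
      clear <- i == L || r == m || conf[r + 1] > i + ell
      if (clear) clear_num[i - 1L] <- clear_num[i - 1L] + w
      allowed <- i == L || r == m || conf[r + 1] >= i + ell + 1L
      if (allowed) J_bond[i - 1L] <- J_bond[i - 1L] + k[i] * w
    }
  }
  J <- k[L] * rho[L - 1L]
  clearance <- ifelse(rho > 0, clear_num / rho, NA_real_)
  prof <- density_profile(p$gene_id, rho, J / alpha, "EXACT", ell)
  attr(prof, "J") <- J
  attr(prof, "J_bond") <- J_bond
  attr(prof, "J_init") <- J_init
  attr(prof, "clearance") <- clearance
  attr(prof, "pi") <- pi_vec
  prof
}
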