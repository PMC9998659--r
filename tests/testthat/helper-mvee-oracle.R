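# Primal interior-point MVEE oracle: ellipsoid {x: ||Ax + b|| <= 1},
# minimize -logdet(A) s.t. ||A p_i + b||^2 < 1, via log-barrier + damped
# Newton with analytic gradient/Hessian. Independent of the Khachiyan
# coordinate-ascent implementation it cross-checks.
mvee_oracle <- function(P, t_max = 1e10) {
  n <- nrow(P)
  # symmetric basis for the 6 upper-triangle parameters of A
  ut_idx <- which(upper.tri(diag(3), diag = TRUE), arr.ind = TRUE)
  basis <- lapply(seq_len(6), function(k) {
    E <- matrix(0, 3, 3)
    E[ut_idx[k, 1], ut_idx[k, 2]] <- 1
    E[ut_idx[k, 2], ut_idx[k, 1]] <- 1
    E
  })
  unpack <- function(par) {
    A <- matrix(0, 3, 3)
    A[upper.tri(A, diag = TRUE)] <- par[1:6]
    A <- A + t(A) - diag(diag(A))
    list(A = A, b = par[7:9])
  }
  gsym <- function(G) {
    G2 <- G + t(G) - diag(diag(G))
    G2[upper.tri(G2, diag = TRUE)]
  }
  feas <- function(par) {
    m <- unpack(par)
    ev <- eigen(m$A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(FALSE)
    r <- P %*% m$A + matrix(m$b, n, 3, byrow = TRUE)
    max(rowSums(r^2)) < 1 - 1e-14
  }
  fval <- function(par, t) {
    m <- unpack(par)
    ev <- eigen(m$A, symmetric = TRUE, only.values = TRUE)$values
    r2 <- rowSums((P %*% m$A + matrix(m$b, n, 3, byrow = TRUE))^2)
    t * (-sum(log(ev))) - sum(log1p(-r2))
  }
  g_logdet <- function(par) {
    c(gsym(-solve(unpack(par)$A)), numeric(3))
  }
  grad_hess <- function(par, t) {
    m <- unpack(par)
    r <- P %*% m$A + matrix(m$b, n, 3, byrow = TRUE)   # n x 3
    s <- 1 - rowSums(r^2)
    g <- numeric(9)
    H <- matrix(0, 9, 9)
    JA <- array(0, c(3, 6, n))
    for (k in 1:6) JA[, k, ] <- tcrossprod(basis[[k]], P)
    for (i in seq_len(n)) {
      J <- cbind(JA[, , i], diag(3))
      Jr <- drop(crossprod(J, r[i, ]))
      g <- g + (2 / s[i]) * Jr
      H <- H + (2 / s[i]) * crossprod(J) + (4 / s[i]^2) * tcrossprod(Jr)
    }
    gl <- g_logdet(par)
    # Hessian of -logdet(A) by central differences of its analytic
    # gradient (t-independent, O(1) scale, so FD noise is negligible)
    Hl <- matrix(0, 9, 9)
    h <- 1e-6
    for (k in 1:6) {
      e <- numeric(9); e[k] <- h
      Hl[, k] <- (g_logdet(par + e) - g_logdet(par - e)) / (2 * h)
    }
    Hl <- (Hl + t(Hl)) / 2
    list(g = t * gl + g, H = t * Hl + H)
  }
  ctr <- colMeans(P)
  R <- 2 * sqrt(max(rowSums(sweep(P, 2, ctr)^2)))
  A0 <- diag(3) / R
  par <- c(A0[upper.tri(A0, diag = TRUE)], as.numeric(-A0 %*% ctr))
  for (t in 10^(0:round(log10(t_max)))) {
    for (it in 1:60) {
      gh <- grad_hess(par, t)
      step <- tryCatch(
        -solve(gh$H + diag(1e-12 * max(abs(diag(gh$H))), 9), gh$g),
        error = function(e) -gh$g / sqrt(sum(gh$g^2)))
      if (sum(gh$g * step) > 0) step <- -step
      f0 <- fval(par, t)
      alpha <- 1
      repeat {
        cand <- par + alpha * step
        if (feas(cand) && fval(cand, t) <= f0) break
        alpha <- alpha / 2
        if (alpha < 1e-14) { cand <- par; break }
      }
      moved <- sqrt(sum((cand - par)^2))
      par <- cand
      dec <- -sum(gh$g * step)     # Newton decrement^2
      if (moved < 1e-14 || dec < 1e-12 * max(1, t)) break
    }
  }
  m <- unpack(par)
  list(volume = 4 / 3 * pi / det(m$A), A = m$A, b = m$b)
}
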