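# Naive brute-force oracles: straightforward enumeration implementations,
# deliberately written with explicit loops and first-principles formulas,
# used to cross-check the package's texture machinery.

oracle_dirs <- function() {
  d <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    v <- c(dx, dy, dz)
    # keep one representative of each +-pair
    if (any(sapply(d, function(e) all(e == -v)))) next
    d[[length(d) + 1L]] <- v
  }
  d
}

oracle_in <- function(p, dm) all(p >= 1L) && all(p <= dm)

# symmetric GLCM counts of one direction by explicit pair enumeration
oracle_glcm_counts <- function(lev, valid, L, dir) {
  dm <- dim(lev)
  m <- matrix(0, L, L)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!valid[x, y, z]) next
    q <- c(x, y, z) + dir
    if (!oracle_in(q, dm)) next
    if (!valid[q[1], q[2], q[3]]) next
    i <- lev[x, y, z]; j <- lev[q[1], q[2], q[3]]
    m[i, j] <- m[i, j] + 1
    m[j, i] <- m[j, i] + 1
  }
  m
}

oracle_glcm_features <- function(counts) {
  iv <- which(rowSums(counts) + colSums(counts) > 0)
  p <- counts[iv, iv, drop = FALSE] / sum(counts)
  n <- length(iv)
  Ng <- n
  px <- rowSums(p)
  mu <- 0
  for (a in 1:n) mu <- mu + iv[a] * px[a]
  sig2 <- 0
  for (a in 1:n) sig2 <- sig2 + (iv[a] - mu)^2 * px[a]
  f <- c(autocorrelation = 0, joint_average = mu, cluster_prominence = 0,
         cluster_shade = 0, cluster_tendency = 0, contrast = 0,
         correlation = 0, difference_average = 0, difference_entropy = 0,
         difference_variance = 0, joint_energy = 0, joint_entropy = 0,
         imc1 = 0, imc2 = 0, idm = 0, idmn = 0, id = 0, idn = 0,
         inverse_variance = 0, maximum_probability = 0, sum_average = 0,
         sum_entropy = 0, sum_squares = 0, mcc = 0)
  pd <- rep(0, max(iv))                  # index k+1 for |i-j| = k
  ps <- rep(0, 2 * max(iv) + 1)         # index k for i+j = k
  hx <- 0
  for (a in 1:n) if (px[a] > 0) hx <- hx - px[a] * log2(px[a])
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (a in 1:n) for (b in 1:n) {
    i <- iv[a]; j <- iv[b]; pij <- p[a, b]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * pij
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - 2 * mu)^4 * pij
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - 2 * mu)^3 * pij
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - 2 * mu)^2 * pij
    f["contrast"] <- f["contrast"] + (i - j)^2 * pij
    f["joint_energy"] <- f["joint_energy"] + pij^2
    if (pij > 0) hxy <- hxy - pij * log2(pij)
    hxy1 <- hxy1 - pij * log2(px[a] * px[b] + 2.220446e-16)
    if (px[a] * px[b] > 0) hxy2 <- hxy2 - px[a] * px[b] * log2(px[a] * px[b])
    f["idm"] <- f["idm"] + pij / (1 + (i - j)^2)
    f["idmn"] <- f["idmn"] + pij / (1 + ((i - j) / Ng)^2)
    f["id"] <- f["id"] + pij / (1 + abs(i - j))
    f["idn"] <- f["idn"] + pij / (1 + abs(i - j) / Ng)
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] + pij / (i - j)^2
    f["sum_squares"] <- f["sum_squares"] + (i - mu)^2 * pij
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + pij
    ps[i + j] <- ps[i + j] + pij
  }
  da <- 0
  for (k in seq_along(pd)) da <- da + (k - 1) * pd[k]
  dv <- 0; de <- 0
  for (k in seq_along(pd)) {
    dv <- dv + ((k - 1) - da)^2 * pd[k]
    if (pd[k] > 0) de <- de - pd[k] * log2(pd[k])
  }
  sa <- 0; se <- 0
  for (k in seq_along(ps)) {
    sa <- sa + k * ps[k]
    if (ps[k] > 0) se <- se - ps[k] * log2(ps[k])
  }
  f["difference_average"] <- da
  f["difference_entropy"] <- de
  f["difference_variance"] <- dv
  f["sum_average"] <- sa
  f["sum_entropy"] <- se
  f["joint_entropy"] <- hxy
  f["correlation"] <- if (sig2 < 1e-24) 1 else
    (f[["autocorrelation"]] - mu^2) / sig2
  f["imc1"] <- if (hx < 1e-12) 0 else (hxy - hxy1) / hx
  f["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f["maximum_probability"] <- max(p)
  if (n == 1) {
    f["mcc"] <- 1
  } else {
    Q <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n) {
      acc <- 0
      for (k in 1:n) acc <- acc + p[a, k] * p[b, k] / (px[a] * px[k])
      Q[a, b] <- acc
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    f["mcc"] <- sqrt(max(0, min(1, ev[2])))
  }
  f
}

# run-length counts of one direction by walking every line voxel by voxel
oracle_glrlm_counts <- function(lev, valid, L, dir, Jmax) {
  dm <- dim(lev)
  m <- matrix(0, L, Jmax)
  counted <- array(FALSE, dm)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!valid[x, y, z] || counted[x, y, z]) next
    prev <- c(x, y, z) - dir
    if (oracle_in(prev, dm) && valid[prev[1], prev[2], prev[3]] &&
        lev[prev[1], prev[2], prev[3]] == lev[x, y, z]) next
    g <- lev[x, y, z]
    len <- 0
    q <- c(x, y, z)
    while (oracle_in(q, dm) && valid[q[1], q[2], q[3]] &&
           lev[q[1], q[2], q[3]] == g) {
      counted[q[1], q[2], q[3]] <- TRUE
      len <- len + 1
      q <- q + dir
    }
    m[g, len] <- m[g, len] + 1
  }
  m
}

oracle_rl_features <- function(m, Nv) {
  Nr <- sum(m)
  sre <- lre <- lglre <- hglre <- srlgle <- srhgle <- lrlgle <- lrhgle <- 0
  glv <- rv <- re <- 0
  mu_i <- mu_j <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    pij <- m[i, j] / Nr
    mu_i <- mu_i + i * pij
    mu_j <- mu_j + j * pij
  }
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    r <- m[i, j]
    if (r == 0) next
    pij <- r / Nr
    sre <- sre + r / j^2
    lre <- lre + r * j^2
    lglre <- lglre + r / i^2
    hglre <- hglre + r * i^2
    srlgle <- srlgle + r / (i^2 * j^2)
    srhgle <- srhgle + r * i^2 / j^2
    lrlgle <- lrlgle + r * j^2 / i^2
    lrhgle <- lrhgle + r * i^2 * j^2
    glv <- glv + (i - mu_i)^2 * pij
    rv <- rv + (j - mu_j)^2 * pij
    re <- re - pij * log2(pij)
  }
  gln <- sum(rowSums(m)^2) / Nr
  rln <- sum(colSums(m)^2) / Nr
  c(sre = sre / Nr, lre = lre / Nr, gln = gln, glnn = gln / Nr,
    rln = rln, rlnn = rln / Nr, rp = Nr / Nv, glv = glv, rv = rv, re = re,
    lglre = lglre / Nr, hglre = hglre / Nr, srlgle = srlgle / Nr,
    srhgle = srhgle / Nr, lrlgle = lrlgle / Nr, lrhgle = lrhgle / Nr)
}

# size zones by repeated neighbourhood expansion (26-connectivity)
oracle_glszm_counts <- function(lev, valid, L) {
  dm <- dim(lev)
  Nvalid <- sum(valid != 0)
  m <- matrix(0, L, max(1, Nvalid))
  seen <- array(FALSE, dm)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!valid[x, y, z] || seen[x, y, z]) next
    g <- lev[x, y, z]
    zone <- array(FALSE, dm)
    zone[x, y, z] <- TRUE
    repeat {
      grew <- FALSE
      idx <- which(zone, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          q <- idx[r, ] + c(dx, dy, dz)
          if (!oracle_in(q, dm)) next
          if (zone[q[1], q[2], q[3]]) next
          if (valid[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == g) {
            zone[q[1], q[2], q[3]] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    seen[zone] <- TRUE
    sz <- sum(zone)
    m[g, sz] <- m[g, sz] + 1
  }
  m
}

oracle_ngtdm <- function(lev, valid, L) {
  dm <- dim(lev)
  n_i <- rep(0, L)
  s_i <- rep(0, L)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!valid[x, y, z]) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (oracle_in(q, dm) && valid[q[1], q[2], q[3]])
        nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (length(nb) == 0) next
    g <- lev[x, y, z]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  cbind(n_i, s_i)
}

oracle_ngtdm_features <- function(M) {
  n_i <- M[, 1]; s_i <- M[, 2]
  Nvp <- sum(n_i)
  pres <- which(n_i > 0)
  Ngp <- length(pres)
  p <- n_i / Nvp
  ps <- 0
  for (i in pres) ps <- ps + p[i] * s_i[i]
  coars <- if (ps <= 0) 1e6 else 1 / ps
  contr <- 0; busy_d <- 0; compl <- 0; stren <- 0
  for (i in pres) for (j in pres) {
    contr <- contr + p[i] * p[j] * (i - j)^2
    busy_d <- busy_d + abs(i * p[i] - j * p[j])
    compl <- compl + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) /
      (p[i] + p[j])
    stren <- stren + (p[i] + p[j]) * (i - j)^2
  }
  contr <- if (Ngp <= 1) 0 else contr / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  c(coarseness = coars, contrast = contr,
    busyness = if (busy_d <= 0) 0 else ps / busy_d,
    complexity = compl / Nvp,
    strength = if (sum(s_i) <= 0) 0 else stren / sum(s_i))
}

oracle_gldm <- function(lev, valid, L, alpha = 0) {
  dm <- dim(lev)
  m <- matrix(0, L, 27)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!valid[x, y, z]) next
    g <- lev[x, y, z]
    dep <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (oracle_in(q, dm) && valid[q[1], q[2], q[3]] &&
          abs(lev[q[1], q[2], q[3]] - g) <= alpha)
        dep <- dep + 1
    }
    m[g, dep] <- m[g, dep] + 1
  }
  m
}

oracle_gldm_features <- function(m, Nv) {
  v <- oracle_rl_features(m, Nv)
  c(sde = v[["sre"]], lde = v[["lre"]], gln = v[["gln"]],
    dn = v[["rln"]], dnn = v[["rlnn"]], glv = v[["glv"]], dv = v[["rv"]],
    de = v[["re"]], lgle = v[["lglre"]], hgle = v[["hglre"]],
    sdlgle = v[["srlgle"]], sdhgle = v[["srhgle"]],
    ldlgle = v[["lrlgle"]], ldhgle = v[["lrhgle"]])
}

# naive first-order oracle using base R directly
oracle_first_order <- function(v, n_bins = 16, voxvol = 1) {
  n <- length(v)
  m2 <- mean((v - mean(v))^2)
  lev <- if (max(v) > min(v)) {
    pmin(floor((v - min(v)) / ((max(v) - min(v)) / n_bins)) + 1, n_bins)
  } else rep(1, n)
  p <- as.vector(table(factor(lev, levels = 1:n_bins))) / n
  p <- p[p > 0]
  q <- unname(quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  rsel <- v >= q[1] & v <= q[5]
  c(energy = sum(v^2), total_energy = sum(v^2) * voxvol,
    entropy = -sum(p * log2(p)), minimum = min(v), p10 = q[1], p90 = q[5],
    maximum = max(v), mean = mean(v), median = q[3], iqr = q[4] - q[2],
    range = max(v) - min(v), mad = mean(abs(v - mean(v))),
    rmad = if (any(rsel)) mean(abs(v[rsel] - mean(v[rsel]))) else 0,
    rms = sqrt(mean(v^2)), stddev = sqrt(m2),
    skewness = if (m2 > 0) mean((v - mean(v))^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((v - mean(v))^4) / m2^2 else 0,
    variance = m2, uniformity = sum(p^2))
}

# brute-force Otsu: evaluate the between-class variance of every candidate
# cut directly on the raw values
oracle_otsu <- function(values, n_bins = 256) {
  mn <- min(values); mx <- max(values)
  cuts <- mn + (mx - mn) * seq_len(n_bins - 1) / n_bins
  best <- -Inf; best_cuts <- c()
  for (tc in cuts) {
    lo <- values[values < tc + 1e-300]
    # histogram-consistent split: values in bins 1..k vs the rest
    k <- pmin(floor((values - mn) / ((mx - mn) / n_bins)), n_bins - 1)
    kc <- round((tc - mn) / ((mx - mn) / n_bins)) - 1
    sel <- k <= kc
    w0 <- mean(sel)
    if (w0 <= 0 || w0 >= 1) next
    # bin-centre means as in a 256-bin histogram method
    ctr <- mn + (k + 0.5) * (mx - mn) / n_bins
    sb <- w0 * (1 - w0) * (mean(ctr[sel]) - mean(ctr[!sel]))^2
    if (sb > best + 1e-15) { best <- sb; best_cuts <- tc }
    else if (sb > best - 1e-15) best_cuts <- c(best_cuts, tc)
  }
  mean(best_cuts)
}
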