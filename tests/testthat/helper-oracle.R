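# Independent brute-force oracles for texture and first-order features.
# Deliberately written as plain double loops over pixels and matrix cells,
# sharing no code with the package implementation.

oracle_eps <- 2.220446e-16

oracle_glcm_matrix <- function(lv, dr, dc, ng) {
  P <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lv))) for (cc in seq_len(ncol(lv))) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nrow(lv) && c2 >= 1 && c2 <= ncol(lv)) {
      a <- lv[r, cc]; b <- lv[r2, c2]
      if (!is.na(a) && !is.na(b)) {
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1 # symmetric
      }
    }
  }
  P
}

oracle_glcm_features_one <- function(P) {
  ng <- nrow(P)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  ux <- 0; for (i in 1:ng) ux <- ux + i * px[i]
  uy <- 0; for (j in 1:ng) uy <- uy + j * py[j]
  sx <- 0; for (i in 1:ng) sx <- sx + (i - ux)^2 * px[i]
  sy <- 0; for (j in 1:ng) sy <- sy + (j - uy)^2 * py[j]
  sx <- sqrt(sx); sy <- sqrt(sy)
  autoc <- cpro <- csha <- cten <- contr <- idv <- idmv <- idmn <- idn <-
    invv <- je <- jent <- ss <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    autoc <- autoc + p * i * j
    cpro <- cpro + p * (i + j - ux - uy)^4
    csha <- csha + p * (i + j - ux - uy)^3
    cten <- cten + p * (i + j - ux - uy)^2
    contr <- contr + p * (i - j)^2
    idv <- idv + p / (1 + abs(i - j))
    idmv <- idmv + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invv <- invv + p / (i - j)^2
    je <- je + p^2
    jent <- jent - p * log2(p + oracle_eps)
    ss <- ss + p * (i - ux)^2
    hxy1 <- hxy1 - p * log2(px[i] * py[j] + oracle_eps)
    hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + oracle_eps)
  }
  pd <- rep(0, ng); ps <- rep(0, 2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  dent <- 0; for (k in 0:(ng - 1)) dent <- dent - pd[k + 1] *
      log2(pd[k + 1] + oracle_eps)
  dvar <- 0; for (k in 0:(ng - 1)) dvar <- dvar + (k - da)^2 * pd[k + 1]
  sa <- 0; sent <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * ps[k]
    sent <- sent - ps[k] * log2(ps[k] + oracle_eps)
  }
  hx <- 0; for (i in 1:ng) hx <- hx - px[i] * log2(px[i] + oracle_eps)
  hy <- 0; for (j in 1:ng) hy <- hy - py[j] * log2(py[j] + oracle_eps)
  imc1 <- if (max(hx, hy) > 0) (jent - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= jent) sqrt(1 - exp(-2 * (hxy2 - jent))) else 0
  corr <- if (sx * sy > 0) (autoc - ux * uy) / (sx * sy) else 1
  pres <- which(px > 0)
  mcc <- if (length(pres) < 2) 1 else {
    Q <- matrix(0, length(pres), length(pres))
    for (a in seq_along(pres)) for (b in seq_along(pres)) {
      acc <- 0
      for (kk in seq_along(pres)) {
        acc <- acc + P[pres[a], pres[kk]] * P[pres[b], pres[kk]] /
          (px[pres[a]] * py[pres[kk]])
      }
      Q[a, b] <- acc
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  c(Autocorrelation = autoc, ClusterProminence = cpro, ClusterShade = csha,
    ClusterTendency = cten, Contrast = contr, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, Id = idv, Idm = idmv, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = invv, JointAverage = ux,
    JointEnergy = je, JointEntropy = jent, MCC = mcc,
    MaximumProbability = max(P), SumAverage = sa, SumEntropy = sent,
    SumSquares = ss)
}

oracle_glcm_features <- function(lv, ng, distances = 1:5) {
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  acc <- NULL
  for (d in distances) for (dir in dirs) {
    v <- oracle_glcm_features_one(oracle_glcm_matrix(lv, dir[1] * d,
                                                     dir[2] * d, ng))
    acc <- if (is.null(acc)) rbind(v) else rbind(acc, v)
  }
  colMeans(acc)
}

oracle_runs_one_direction <- function(lv, dr, dc, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  maxlen <- max(nr, nc)
  P <- matrix(0, ng, maxlen)
  # starting cells: those with no predecessor in (-dr, -dc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    pr <- r - dr; pc <- cc - dc
    starts <- pr < 1 || pr > nr || pc < 1 || pc > nc
    if (!starts) next
    # walk the line
    rr <- r; c2 <- cc
    run_val <- NA; run_len <- 0
    while (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
      v <- lv[rr, c2]
      if (is.na(v)) {
        if (!is.na(run_val)) P[run_val, run_len] <- P[run_val, run_len] + 1
        run_val <- NA; run_len <- 0
      } else if (!is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        if (!is.na(run_val)) P[run_val, run_len] <- P[run_val, run_len] + 1
        run_val <- v; run_len <- 1
      }
      rr <- rr + dr; c2 <- c2 + dc
    }
    if (!is.na(run_val)) P[run_val, run_len] <- P[run_val, run_len] + 1
  }
  P
}

oracle_sz_features <- function(P, Np) {
  N <- sum(P)
  p <- P / N
  ng <- nrow(P); nl <- ncol(P)
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- re <- 0
  mu_i <- mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    pp <- p[i, j]
    sre <- sre + pp / j^2; lre <- lre + pp * j^2
    lgl <- lgl + pp / i^2; hgl <- hgl + pp * i^2
    srl <- srl + pp / (i^2 * j^2); srh <- srh + pp * i^2 / j^2
    lrl <- lrl + pp * j^2 / i^2; lrh <- lrh + pp * i^2 * j^2
    re <- re - pp * log2(pp + oracle_eps)
    mu_i <- mu_i + pp * i; mu_j <- mu_j + pp * j
  }
  glv <- rv <- 0
  for (i in 1:ng) for (j in 1:nl) {
    glv <- glv + p[i, j] * (i - mu_i)^2
    rv <- rv + p[i, j] * (j - mu_j)^2
  }
  gln <- sum(rowSums(P)^2) / N
  rln <- sum(colSums(P)^2) / N
  c(sre, lre, gln, gln / N, rln, rln / N, N / Np, glv, rv, re, lgl, hgl,
    srl, srh, lrl, lrh)
}

oracle_glrlm_features <- function(lv, ng) {
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  Np <- sum(!is.na(lv))
  acc <- NULL
  for (d in dirs) {
    P <- oracle_runs_one_direction(lv, d[1], d[2], ng)
    acc <- rbind(acc, oracle_sz_features(P, Np))
  }
  colMeans(acc)
}

oracle_zone_label <- function(lv) {
  # repeated-scan connected-component labelling, 8-connectivity
  nr <- nrow(lv); nc <- ncol(lv)
  lab <- matrix(0L, nr, nc)
  nxt <- 1L
  sizes <- c(); glevels <- c()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(lv[r, cc]) || lab[r, cc] != 0L) next
    # BFS with an explicit frontier list
    frontier <- list(c(r, cc))
    lab[r, cc] <- nxt
    size <- 0L
    while (length(frontier) > 0) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            !is.na(lv[r2, c2]) && lab[r2, c2] == 0L &&
            lv[r2, c2] == lv[r, cc]) {
          lab[r2, c2] <- nxt
          frontier[[length(frontier) + 1]] <- c(r2, c2)
        }
      }
    }
    sizes <- c(sizes, size); glevels <- c(glevels, lv[r, cc])
    nxt <- nxt + 1L
  }
  cbind(glevels, sizes)
}

oracle_glszm_features <- function(lv, ng) {
  z <- oracle_zone_label(lv)
  P <- matrix(0, ng, max(z[, 2]))
  for (i in seq_len(nrow(z))) P[z[i, 1], z[i, 2]] <- P[z[i, 1], z[i, 2]] + 1
  oracle_sz_features(P, sum(!is.na(lv)))
}

oracle_ngtdm_features <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  s <- rep(0, ng); n <- rep(0, ng)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(lv[r, cc])) next
    acc <- 0; cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(lv[r2, c2])) {
        acc <- acc + lv[r2, c2]; cnt <- cnt + 1
      }
    }
    if (cnt > 0) {
      g <- lv[r, cc]
      s[g] <- s[g] + abs(g - acc / cnt)
      n[g] <- n[g] + 1
    }
  }
  Nvp <- sum(n)
  p <- n / Nvp
  pres <- which(n > 0)
  ngp <- length(pres)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- 0
  if (ngp > 1) {
    for (i in pres) for (j in pres) contrast <- contrast +
        p[i] * p[j] * (i - j)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / Nvp
  }
  bd <- 0
  for (i in pres) for (j in pres) bd <- bd + abs(i * p[i] - j * p[j])
  busy <- if (bd > 0) sum(p * s) / bd else 0
  cx <- 0
  for (i in pres) for (j in pres) cx <- cx +
      abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  cx <- cx / Nvp
  st <- 0
  for (i in pres) for (j in pres) st <- st + (p[i] + p[j]) * (i - j)^2
  st <- if (sum(s) > 0) st / sum(s) else 0
  c(coarseness, contrast, busy, cx, st)
}

oracle_gldm_features <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  recs <- NULL
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(lv[r, cc])) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(lv[r2, c2]) && lv[r2, c2] == lv[r, cc]) dep <- dep + 1
    }
    recs <- rbind(recs, c(lv[r, cc], dep + 1))
  }
  nd <- max(recs[, 2])
  P <- matrix(0, ng, nd)
  for (i in seq_len(nrow(recs))) P[recs[i, 1], recs[i, 2]] <-
      P[recs[i, 1], recs[i, 2]] + 1
  Nz <- sum(P)
  p <- P / Nz
  sde <- lde <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- de <- 0
  mu_i <- mu_j <- 0
  for (i in 1:ng) for (j in 1:nd) {
    pp <- p[i, j]
    sde <- sde + pp / j^2; lde <- lde + pp * j^2
    lgl <- lgl + pp / i^2; hgl <- hgl + pp * i^2
    sdl <- sdl + pp / (i^2 * j^2); sdh <- sdh + pp * i^2 / j^2
    ldl <- ldl + pp * j^2 / i^2; ldh <- ldh + pp * i^2 * j^2
    de <- de - pp * log2(pp + oracle_eps)
    mu_i <- mu_i + pp * i; mu_j <- mu_j + pp * j
  }
  glv <- dv <- 0
  for (i in 1:ng) for (j in 1:nd) {
    glv <- glv + p[i, j] * (i - mu_i)^2
    dv <- dv + p[i, j] * (j - mu_j)^2
  }
  c(sde, lde, sum(rowSums(P)^2) / Nz, sum(colSums(P)^2) / Nz,
    sum(colSums(P)^2) / Nz^2, glv, dv, de, lgl, hgl, sdl, sdh, ldl, ldh)
}

oracle_firstorder <- function(x, bin_width = 15, pixel_area = 0.12^2) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  q10 <- quantile(x, 0.1, names = FALSE)
  q90 <- quantile(x, 0.9, names = FALSE)
  sub <- x[x >= q10 & x <= q90]
  h <- table(floor((x - min(x)) / bin_width))
  p <- as.numeric(h) / n
  c(Energy = sum(x^2), TotalEnergy = pixel_area * sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x), `10Percentile` = q10,
    `90Percentile` = q90, Maximum = max(x), Mean = m,
    Median = median(x), InterquartileRange = quantile(x, .75, names = FALSE) -
      quantile(x, .25, names = FALSE),
    Range = max(x) - min(x), MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (v > 0) mean((x - m)^3) / v^1.5 else 0,
    Kurtosis = if (v > 0) mean((x - m)^4) / v^2 else 0,
    Variance = v, Uniformity = sum(p^2))
}

# relative comparison helper with absolute floor for near-zero values
expect_close <- function(a, b, rel = 1e-4, abs_floor = 1e-8) {
  d <- abs(a - b)
  tol <- pmax(abs_floor, rel * pmax(abs(a), abs(b)))
  testthat::expect_true(all(d <= tol),
                        info = paste0("max rel dev ",
                                      format(max(d / pmax(abs(b), 1e-12)))))
}

# Mann-Whitney-based AUROC (independent of the trapezoid path)
oracle_auroc_mw <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  u <- 0
  for (a in s1) for (b in s0) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(s1) * length(s0))
}
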