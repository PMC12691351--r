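# Gray-level texture-matrix features over masked 2-D images.
#
# All functions take a discretized level image: an integer matrix with bin
# numbers 1..n_levels inside the mask and NA outside. Feature definitions
# follow the IBSI-consistent conventions of the standard radiomics feature
# sets: GLCM (24), GLRLM (16), GLSZM (16), NGTDM (5), GLDM (14).

.tex_eps <- 2.220446e-16

# co-occurrence counts for one (dr, dc) offset, symmetrized
.glcm_matrix <- function(lv, dr, dc, n_levels) {
  nr <- nrow(lv); nc <- ncol(lv)
  r0 <- max(1, 1 - dr):min(nr, nr - dr)
  c0 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- lv[r0, c0, drop = FALSE]
  b <- lv[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  cnt <- tabulate(a[ok] + (b[ok] - 1L) * n_levels, nbins = n_levels^2)
  P <- matrix(cnt, n_levels, n_levels)
  P + t(P)
}

.glcm_feature_values <- function(P) {
  tot <- sum(P)
  nms <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares")
  if (tot == 0) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  P <- P / tot
  Ng <- nrow(P)
  I <- row(P); J <- col(P)
  px <- rowSums(P); py <- colSums(P)
  ux <- sum(seq_len(Ng) * px); uy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - ux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - uy)^2 * py))
  autoc <- sum(P * I * J)
  corr <- if (sx * sy > 0) (autoc - ux * uy) / (sx * sy) else 1
  kd <- 0:(Ng - 1)
  p_diff <- vapply(kd, function(k) sum(P[abs(I - J) == k]), numeric(1))
  da <- sum(kd * p_diff)
  ks <- 2:(2 * Ng)
  p_sum <- vapply(ks, function(k) sum(P[I + J == k]), numeric(1))
  H <- -sum(P * log2(P + .tex_eps))
  HX <- -sum(px * log2(px + .tex_eps))
  HY <- -sum(py * log2(py + .tex_eps))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * log2(pxpy + .tex_eps))
  HXY2 <- -sum(pxpy * log2(pxpy + .tex_eps))
  imc1 <- if (max(HX, HY) > 0) (H - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= H) sqrt(1 - exp(-2 * (HXY2 - H))) else 0
  # MCC: second-largest eigenvalue of the Markov-like matrix Q
  present <- which(px > 0)
  mcc <- if (length(present) < 2) 1 else {
    Pp <- P[present, present, drop = FALSE]
    A <- Pp / (px[present] %o% py[present])
    Q <- A %*% t(Pp)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  vals <- c(
    Autocorrelation = autoc,
    ClusterProminence = sum(P * (I + J - ux - uy)^4),
    ClusterShade = sum(P * (I + J - ux - uy)^3),
    ClusterTendency = sum(P * (I + J - ux - uy)^2),
    Contrast = sum(P * (I - J)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff * log2(p_diff + .tex_eps)),
    DifferenceVariance = sum((kd - da)^2 * p_diff),
    Id = sum(P / (1 + abs(I - J))),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + (I - J)^2 / Ng^2)),
    Idn = sum(P / (1 + abs(I - J) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[I != J] / (I[I != J] - J[I != J])^2),
    JointAverage = ux,
    JointEnergy = sum(P^2),
    JointEntropy = H,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * p_sum),
    SumEntropy = -sum(p_sum * log2(p_sum + .tex_eps)),
    SumSquares = sum(P * (I - ux)^2))
  vals[nms]
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence matrices are built for the four 2-D directions at
#' each configured distance; the 24 feature values are averaged over all
#' direction-by-distance matrices.
#'
#' @param lv level image (integer matrix, NA outside the mask).
#' @param n_levels number of gray levels.
#' @param distances integer offsets (default 1:5).
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(lv, n_levels, distances = 1:5) {
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  mats <- list()
  for (d in distances) for (dir in dirs) {
    mats[[length(mats) + 1]] <- .glcm_matrix(lv, dir[1] * d, dir[2] * d,
                                             n_levels)
  }
  vals <- vapply(mats, .glcm_feature_values, numeric(24))
  out <- rowMeans(vals, na.rm = TRUE)
  names(out) <- paste0("glcm_", rownames(vals))
  out
}

# run-length matrix for one direction; lines are extracted, broken at NA,
# and run lengths of equal levels accumulated
.glrlm_matrix <- function(lv, direction, n_levels) {
  nr <- nrow(lv); nc <- ncol(lv)
  rr <- as.vector(row(lv)); cc <- as.vector(col(lv))
  key <- switch(direction,
                h = rr, v = cc, d = cc - rr, a = cc + rr)
  within <- switch(direction, h = cc, v = rr, d = rr, a = rr)
  ord <- order(key, within)
  v <- as.vector(lv)[ord]
  seg_id <- cumsum(c(TRUE, diff(key[ord]) != 0))
  P <- matrix(0, n_levels, max(nr, nc))
  for (s in split(v, seg_id)) {
    r <- rle(ifelse(is.na(s), -1L, s))
    keep <- r$values > 0
    for (i in which(keep)) {
      P[r$values[i], r$lengths[i]] <- P[r$values[i], r$lengths[i]] + 1
    }
  }
  P
}

.rl_feature_values <- function(P, Np, prefix, jname) {
  Nr <- sum(P)
  nm <- function(x) paste0(prefix, "_", x)
  ivec <- seq_len(nrow(P)); jvec <- seq_len(ncol(P))
  if (Nr == 0) {
    return(NULL)
  }
  p <- P / Nr
  ri <- rowSums(P); cj <- colSums(P)
  mu_i <- sum(ivec * rowSums(p)); mu_j <- sum(jvec * colSums(p))
  Imat <- matrix(ivec, nrow(P), ncol(P))
  Jmat <- matrix(jvec, nrow(P), ncol(P), byrow = TRUE)
  vals <- c(
    sum(p / Jmat^2),
    sum(p * Jmat^2),
    sum(ri^2) / Nr,
    sum(ri^2) / Nr^2,
    sum(cj^2) / Nr,
    sum(cj^2) / Nr^2,
    Nr / Np,
    sum(p * (Imat - mu_i)^2),
    sum(p * (Jmat - mu_j)^2),
    -sum(p * log2(p + .tex_eps)),
    sum(p / Imat^2),
    sum(p * Imat^2),
    sum(p / (Imat^2 * Jmat^2)),
    sum(p * Imat^2 / Jmat^2),
    sum(p * Jmat^2 / Imat^2),
    sum(p * Imat^2 * Jmat^2))
  names(vals) <- nm(c(
    paste0("Short", jname, "Emphasis"),
    paste0("Long", jname, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(jname, "NonUniformity"), paste0(jname, "NonUniformityNormalized"),
    paste0(jname, "Percentage"),
    "GrayLevelVariance", paste0(jname, "Variance"),
    paste0(jname, "Entropy"),
    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    paste0("Short", jname, "LowGrayLevelEmphasis"),
    paste0("Short", jname, "HighGrayLevelEmphasis"),
    paste0("Long", jname, "LowGrayLevelEmphasis"),
    paste0("Long", jname, "HighGrayLevelEmphasis")))
  vals
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices are built per direction (horizontal, vertical, both
#' diagonals), runs breaking at mask boundaries; the 16 features are averaged
#' over directions.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(lv, n_levels) {
  Np <- sum(!is.na(lv))
  dirs <- c("h", "v", "d", "a")
  vals <- vapply(dirs, function(d) {
    .rl_feature_values(.glrlm_matrix(lv, d, n_levels), Np, "glrlm", "Run")
  }, numeric(16))
  out <- rowMeans(vals)
  # canonical radiomics feature naming
  names(out) <- c("glrlm_ShortRunEmphasis", "glrlm_LongRunEmphasis",
                  "glrlm_GrayLevelNonUniformity",
                  "glrlm_GrayLevelNonUniformityNormalized",
                  "glrlm_RunLengthNonUniformity",
                  "glrlm_RunLengthNonUniformityNormalized",
                  "glrlm_RunPercentage", "glrlm_GrayLevelVariance",
                  "glrlm_RunVariance", "glrlm_RunEntropy",
                  "glrlm_LowGrayLevelRunEmphasis",
                  "glrlm_HighGrayLevelRunEmphasis",
                  "glrlm_ShortRunLowGrayLevelEmphasis",
                  "glrlm_ShortRunHighGrayLevelEmphasis",
                  "glrlm_LongRunLowGrayLevelEmphasis",
                  "glrlm_LongRunHighGrayLevelEmphasis")
  out
}

# 8-connected zone labelling via iterative flood fill
.zone_sizes <- function(lv, n_levels) {
  nr <- nrow(lv); nc <- ncol(lv)
  lab <- matrix(0L, nr, nc)
  zones <- list()
  stack <- integer(nr * nc)
  nbr_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(!is.na(lv) & lab == 0L)) {
    if (lab[start] != 0L) next
    g <- lv[start]
    sp <- 1L
    stack[1L] <- start
    lab[start] <- 1L
    size <- 0L
    while (sp > 0L) {
      cur <- stack[sp]; sp <- sp - 1L
      size <- size + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r2 <- r + nbr_dr[k]; c2 <- cc + nbr_dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          idx <- (c2 - 1L) * nr + r2
          if (lab[idx] == 0L && !is.na(lv[idx]) && lv[idx] == g) {
            lab[idx] <- 1L
            sp <- sp + 1L
            stack[sp] <- idx
          }
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)
}

#' Gray-level size-zone matrix features
#'
#' A single zone-size matrix over 8-connected zones of equal gray level; 16
#' features.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(lv, n_levels) {
  Np <- sum(!is.na(lv))
  if (Np == 0) stop("empty mask for GLSZM")
  z <- .zone_sizes(lv, n_levels)
  P <- matrix(0, n_levels, max(z[, 2]))
  for (i in seq_len(nrow(z))) P[z[i, 1], z[i, 2]] <- P[z[i, 1], z[i, 2]] + 1
  vals <- .rl_feature_values(P, Np, "glszm", "Zone")
  names(vals) <- c("glszm_SmallAreaEmphasis", "glszm_LargeAreaEmphasis",
                   "glszm_GrayLevelNonUniformity",
                   "glszm_GrayLevelNonUniformityNormalized",
                   "glszm_SizeZoneNonUniformity",
                   "glszm_SizeZoneNonUniformityNormalized",
                   "glszm_ZonePercentage", "glszm_GrayLevelVariance",
                   "glszm_ZoneVariance", "glszm_ZoneEntropy",
                   "glszm_LowGrayLevelZoneEmphasis",
                   "glszm_HighGrayLevelZoneEmphasis",
                   "glszm_SmallAreaLowGrayLevelEmphasis",
                   "glszm_SmallAreaHighGrayLevelEmphasis",
                   "glszm_LargeAreaLowGrayLevelEmphasis",
                   "glszm_LargeAreaHighGrayLevelEmphasis")
  vals
}

# shifted neighbor sums/counts over the 8-neighborhood (Chebyshev distance 1)
.neighbor_stats <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  val <- lv
  val[is.na(val)] <- 0
  ok <- !is.na(lv)
  nsum <- matrix(0, nr, nc)
  ncnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    tgt_r <- rs - dr; tgt_c <- cs - dc
    nsum[tgt_r, tgt_c] <- nsum[tgt_r, tgt_c] + val[rs, cs]
    ncnt[tgt_r, tgt_c] <- ncnt[tgt_r, tgt_c] + ok[rs, cs]
  }
  list(sum = nsum, count = ncnt)
}

#' Neighborhood gray-tone difference matrix features
#'
#' Distance-1 (8-neighbor) neighborhood; 5 features: coarseness, contrast,
#' busyness, complexity, strength.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(lv, n_levels) {
  ns <- .neighbor_stats(lv)
  valid <- !is.na(lv) & ns$count > 0
  if (!any(valid)) stop("empty mask for NGTDM")
  x <- lv[valid]
  mu_n <- ns$sum[valid] / ns$count[valid]
  diffs <- abs(x - mu_n)
  n_i <- tabulate(x, nbins = n_levels)
  s_i <- vapply(seq_len(n_levels), function(g) sum(diffs[x == g]), numeric(1))
  Nvp <- sum(n_i)
  p_i <- n_i / Nvp
  present <- which(n_i > 0)
  Ngp <- length(present)
  i <- present
  coars_den <- sum(p_i * s_i)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (Ngp > 1) {
    (sum(outer(p_i[i], p_i[i]) * outer(i, i, "-")^2) / (Ngp * (Ngp - 1))) *
      (sum(s_i) / Nvp)
  } else 0
  busy_den <- sum(abs(outer(i * p_i[i], i * p_i[i], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  cmplx <- sum(abs(outer(i, i, "-")) *
                 (outer(p_i[i] * s_i[i], p_i[i] * s_i[i], "+")) /
                 outer(p_i[i], p_i[i], "+")) / Nvp
  strength <- if (sum(s_i) > 0) {
    sum(outer(p_i[i], p_i[i], "+") * outer(i, i, "-")^2) / sum(s_i)
  } else 0
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = cmplx,
    ngtdm_Strength = strength)
}

#' Gray-level dependence matrix features
#'
#' Distance-1 neighborhood, dependence tolerance 0: a neighbor is dependent
#' when its level equals the centre's. The dependence index is the dependent
#' count plus one. 14 features.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(lv, n_levels) {
  nr <- nrow(lv); nc <- ncol(lv)
  ok <- !is.na(lv)
  if (!any(ok)) stop("empty mask for GLDM")
  dep <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    tgt_r <- rs - dr; tgt_c <- cs - dc
    eq <- !is.na(lv[rs, cs]) & !is.na(lv[tgt_r, tgt_c]) &
      lv[rs, cs] == lv[tgt_r, tgt_c]
    dep[tgt_r, tgt_c] <- dep[tgt_r, tgt_c] + eq
  }
  depv <- dep[ok] + 1L
  g <- lv[ok]
  Nd <- max(depv)
  P <- matrix(0, n_levels, Nd)
  cnt <- tabulate(g + (depv - 1L) * n_levels, nbins = n_levels * Nd)
  P[] <- cnt
  Nz <- sum(P)
  p <- P / Nz
  ivec <- seq_len(n_levels); jvec <- seq_len(Nd)
  Imat <- matrix(ivec, n_levels, Nd)
  Jmat <- matrix(jvec, n_levels, Nd, byrow = TRUE)
  mu_i <- sum(Imat * p); mu_j <- sum(Jmat * p)
  c(gldm_SmallDependenceEmphasis = sum(p / Jmat^2),
    gldm_LargeDependenceEmphasis = sum(p * Jmat^2),
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    gldm_GrayLevelVariance = sum(p * (Imat - mu_i)^2),
    gldm_DependenceVariance = sum(p * (Jmat - mu_j)^2),
    gldm_DependenceEntropy = -sum(p * log2(p + .tex_eps)),
    gldm_LowGrayLevelEmphasis = sum(p / Imat^2),
    gldm_HighGrayLevelEmphasis = sum(p * Imat^2),
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(p / (Imat^2 * Jmat^2)),
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(p * Imat^2 / Jmat^2),
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(p * Jmat^2 / Imat^2),
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(p * Imat^2 * Jmat^2))
}

#' Texture features for one family
#'
#' @param lv level image (integer matrix with NA outside the mask).
#' @param n_levels number of levels.
#' @param family one of "glcm", "glrlm", "glszm", "ngtdm", "gldm".
#' @param distances GLCM distances.
#' @return named numeric vector (24/16/16/5/14 values).
#' @export
texture_features <- function(lv, n_levels,
                             family = c("glcm", "glrlm", "glszm", "ngtdm",
                                        "gldm"),
                             distances = 1:5) {
  family <- match.arg(family)
  if (sum(!is.na(lv)) == 0) stop("empty mask for texture features")
  switch(family,
         glcm = glcm_features(lv, n_levels, distances),
         glrlm = glrlm_features(lv, n_levels),
         glszm = glszm_features(lv, n_levels),
         ngtdm = ngtdm_features(lv, n_levels),
         gldm = gldm_features(lv, n_levels))
}
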