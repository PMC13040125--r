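# Independent brute-force oracles: naive loops over the printed formulas,
# sharing no code with the package implementation.

bf_offsets <- function() list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))

bf_glcm_matrix <- function(levels, ng, distance = 1) {
  P <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (off in bf_offsets()) {
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        a <- levels[r, c]
        if (a == 0) next
        r2 <- r + off[1] * distance; c2 <- c + off[2] * distance
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        b <- levels[r2, c2]
        if (b == 0) next
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P / sum(P)
}

bf_glcm_features <- function(P) {
  ng <- nrow(P)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  sig2 <- 0
  for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j, P[i, j])
    s
  }
  hxy <- -acc(function(i, j, p) p * lg2(p))
  hx <- -sum(sapply(px, function(p) p * lg2(p)))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    m <- px[i] * px[j]
    hxy1 <- hxy1 - P[i, j] * lg2(m)
    hxy2 <- hxy2 - m * lg2(m)
  }
  single <- sum(px > 0) <= 1
  davg <- sum((0:(ng - 1)) * pd)
  savg <- sum((2:(2 * ng)) * ps)
  out <- c(
    F_cm.joint.max = max(P),
    F_cm.joint.avg = mu,
    F_cm.joint.var = acc(function(i, j, p) (i - mu)^2 * p),
    F_cm.joint.entr = hxy,
    F_cm.diff.avg = davg,
    F_cm.diff.var = sum(((0:(ng - 1)) - davg)^2 * pd),
    F_cm.diff.entr = -sum(sapply(pd, function(p) p * lg2(p))),
    F_cm.sum.avg = savg,
    F_cm.sum.var = sum(((2:(2 * ng)) - savg)^2 * ps),
    F_cm.sum.entr = -sum(sapply(ps, function(p) p * lg2(p))),
    F_cm.energy = acc(function(i, j, p) p^2),
    F_cm.contrast = acc(function(i, j, p) (i - j)^2 * p),
    F_cm.dissimilarity = acc(function(i, j, p) abs(i - j) * p),
    F_cm.inv.diff = acc(function(i, j, p) p / (1 + abs(i - j))),
    F_cm.inv.diff.norm = acc(function(i, j, p) p / (1 + abs(i - j) / ng)),
    F_cm.inv.diff.mom = acc(function(i, j, p) p / (1 + (i - j)^2)),
    F_cm.inv.diff.mom.norm = acc(function(i, j, p)
      p / (1 + (i - j)^2 / ng^2)),
    F_cm.inv.var = acc(function(i, j, p) if (i != j) p / (i - j)^2 else 0),
    F_cm.corr = if (single || sig2 == 0) NA_real_ else
      (acc(function(i, j, p) i * j * p) - mu^2) / sig2,
    F_cm.auto.corr = acc(function(i, j, p) i * j * p),
    F_cm.clust.tend = acc(function(i, j, p) (i + j - 2 * mu)^2 * p),
    F_cm.clust.shade = acc(function(i, j, p) (i + j - 2 * mu)^3 * p),
    F_cm.clust.prom = acc(function(i, j, p) (i + j - 2 * mu)^4 * p),
    F_cm.info.corr.1 = if (single || hx == 0) NA_real_ else
      (hxy - hxy1) / hx,
    F_cm.info.corr.2 = if (single) NA_real_ else
      sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)))
  out
}

# enumerate maximal runs by walking each line of each direction
bf_rlm_matrix <- function(levels, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  runs <- list()
  for (off in bf_offsets()) {
    starts <- list()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      pr <- r - off[1]; pc <- c - off[2]
      if (pr < 1 || pr > nr || pc < 1 || pc > nc)
        starts[[length(starts) + 1]] <- c(r, c)
    }
    for (s in starts) {
      r <- s[1]; c <- s[2]
      seq_levels <- integer(0)
      while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
        seq_levels <- c(seq_levels, levels[r, c])
        r <- r + off[1]; c <- c + off[2]
      }
      # split at mask (0) and level changes
      cur <- 0; len <- 0
      for (v in c(seq_levels, -1)) {
        if (v == cur && v != 0) {
          len <- len + 1
        } else {
          if (cur > 0) runs[[length(runs) + 1]] <- c(cur, len)
          cur <- v; len <- if (v > 0) 1 else 0
        }
      }
    }
  }
  lmax <- max(1, sapply(runs, function(x) x[2]))
  R <- matrix(0, ng, lmax)
  for (x in runs) R[x[1], x[2]] <- R[x[1], x[2]] + 1
  R
}

bf_rlm_features <- function(R) {
  ng <- nrow(R); lm <- ncol(R)
  nr <- sum(R)
  np <- 0
  for (g in 1:ng) for (l in 1:lm) np <- np + l * R[g, l]
  sgl <- function(f) {
    s <- 0
    for (g in 1:ng) for (l in 1:lm) s <- s + f(g, l, R[g, l])
    s
  }
  rg <- sapply(1:ng, function(g) sum(R[g, ]))
  rl <- sapply(1:lm, function(l) sum(R[, l]))
  mug <- sgl(function(g, l, x) g * x) / nr
  mul <- sgl(function(g, l, x) l * x) / nr
  lg2 <- function(x) if (x > 0) log2(x) else 0
  c(F_rlm.sre = sum(rl / (1:lm)^2) / nr,
    F_rlm.lre = sum(rl * (1:lm)^2) / nr,
    F_rlm.lgre = sum(rg / (1:ng)^2) / nr,
    F_rlm.hgre = sum(rg * (1:ng)^2) / nr,
    F_rlm.srlge = sgl(function(g, l, x) x / (g^2 * l^2)) / nr,
    F_rlm.srhge = sgl(function(g, l, x) x * g^2 / l^2) / nr,
    F_rlm.lrlge = sgl(function(g, l, x) x * l^2 / g^2) / nr,
    F_rlm.lrhge = sgl(function(g, l, x) x * g^2 * l^2) / nr,
    F_rlm.glnu = sum(rg^2) / nr,
    F_rlm.glnu.norm = sum(rg^2) / nr^2,
    F_rlm.rlnu = sum(rl^2) / nr,
    F_rlm.rlnu.norm = sum(rl^2) / nr^2,
    F_rlm.r.perc = nr / np,
    F_rlm.gl.var = sgl(function(g, l, x) (g - mug)^2 * x / nr),
    F_rlm.rl.var = sgl(function(g, l, x) (l - mul)^2 * x / nr),
    F_rlm.rl.entr = -sgl(function(g, l, x) (x / nr) * lg2(x / nr)))
}

# 8-connected equal-level zones by breadth-first search
bf_szm_matrix <- function(levels, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    g <- levels[r0, c0]
    if (g == 0 || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- cur[1] + dr; c <- cur[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!seen[r, c] && levels[r, c] == g) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  smax <- max(1, sapply(zones, function(z) z[2]))
  S <- matrix(0, ng, smax)
  for (z in zones) S[z[1], z[2]] <- S[z[1], z[2]] + 1
  S
}

bf_szm_features <- function(S) {
  ng <- nrow(S); sm <- ncol(S)
  nz <- sum(S)
  np <- 0
  for (g in 1:ng) for (s in 1:sm) np <- np + s * S[g, s]
  sgl <- function(f) {
    acc <- 0
    for (g in 1:ng) for (s in 1:sm) acc <- acc + f(g, s, S[g, s])
    acc
  }
  sg <- sapply(1:ng, function(g) sum(S[g, ]))
  ss <- sapply(1:sm, function(s) sum(S[, s]))
  mug <- sgl(function(g, s, x) g * x) / nz
  mus <- sgl(function(g, s, x) s * x) / nz
  lg2 <- function(x) if (x > 0) log2(x) else 0
  c(F_szm.sze = sum(ss / (1:sm)^2) / nz,
    F_szm.lze = sum(ss * (1:sm)^2) / nz,
    F_szm.lgze = sum(sg / (1:ng)^2) / nz,
    F_szm.hgze = sum(sg * (1:ng)^2) / nz,
    F_szm.szlge = sgl(function(g, s, x) x / (g^2 * s^2)) / nz,
    F_szm.szhge = sgl(function(g, s, x) x * g^2 / s^2) / nz,
    F_szm.lzlge = sgl(function(g, s, x) x * s^2 / g^2) / nz,
    F_szm.lzhge = sgl(function(g, s, x) x * g^2 * s^2) / nz,
    F_szm.glnu = sum(sg^2) / nz,
    F_szm.glnu.norm = sum(sg^2) / nz^2,
    F_szm.zsnu = sum(ss^2) / nz,
    F_szm.zsnu.norm = sum(ss^2) / nz^2,
    F_szm.z.perc = nz / np,
    F_szm.gl.var = sgl(function(g, s, x) (g - mug)^2 * x / nz),
    F_szm.zs.var = sgl(function(g, s, x) (s - mus)^2 * x / nz),
    F_szm.zs.entr = -sgl(function(g, s, x) (x / nz) * lg2(x / nz)))
}

bf_first_order <- function(v, n_bins = 32) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  lo <- min(v); hi <- max(v)
  p <- if (hi > lo) {
    k <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1, n_bins)
    as.numeric(table(factor(k, levels = 1:n_bins))) / n
  } else c(1, rep(0, n_bins - 1))
  lg2 <- function(x) if (x > 0) log2(x) else 0
  c(F_stat.mean = mu, F_stat.var = m2, F_stat.sd = sqrt(m2),
    F_stat.skew = if (m2 > 0) m3 / m2^1.5 else 0,
    F_stat.kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    F_stat.median = unname(quantile(v, 0.5, names = FALSE)),
    F_stat.min = lo, F_stat.max = hi,
    F_stat.p10 = unname(quantile(v, 0.1)),
    F_stat.p90 = unname(quantile(v, 0.9)),
    F_stat.iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)),
    F_stat.range = hi - lo,
    F_stat.mad = sum(abs(v - mu)) / n,
    F_stat.rms = sqrt(sum(v^2) / n),
    F_stat.energy = sum(v^2),
    F_stat.entropy = -sum(sapply(p, function(x) x * lg2(x))),
    F_stat.uniformity = sum(p^2))
}

# step-up FDR by the printed definition:
# adjusted_i = min over { j : p_j >= p_i } of m * p_j / rank_j, capped at 1
bf_benjamini_hochberg <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  sapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / rk[p >= p[i]]))
  })
}

# all-pairs Mann-Whitney AUC
bf_auc <- function(risks, y) {
  pos <- risks[y == 1]; neg <- risks[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

bf_youden <- function(risks, y) {
  best_j <- -Inf; best_c <- Inf
  for (ct in sort(unique(risks))) {
    sens <- mean(risks[y == 1] >= ct)
    spec <- mean(risks[y == 0] < ct)
    j <- sens + spec - 1
    if (j > best_j || (j == best_j && ct < best_c)) {
      best_j <- j; best_c <- ct
    }
  }
  best_c
}

make_droi <- function(levels, ng = max(levels)) {
  structure(list(levels = matrix(as.integer(levels), nrow(levels)),
                 n_gray = as.integer(ng)),
            class = "discretized_roi")
}

random_droi <- function(seed, nr = 6, nc = 6, ng = 4, p_mask = 0.75) {
  set.seed(seed)
  lev <- matrix(0L, nr, nc)
  inside <- matrix(runif(nr * nc) < p_mask, nr, nc)
  if (sum(inside) < 4) inside[1:2, 1:2] <- TRUE
  lev[inside] <- sample.int(ng, sum(inside), replace = TRUE)
  make_droi(lev, ng)
}

# small cached cohort shared across test files
.test_env <- new.env()
get_small_cohort <- function() {
  if (is.null(.test_env$cohort)) {
    spec <- cohort_spec(n_sarcoma = 30, n_leiomyoma = 30,
                        image_height = 64, image_width = 64,
                        myometrium_fraction = 0.5, seed = 42)
    .test_env$spec <- spec
    .test_env$cohort <- generate_cohort(spec)
  }
  .test_env$cohort
}
get_small_features <- function() {
  if (is.null(.test_env$features))
    .test_env$features <- feature_table(get_small_cohort())
  .test_env$features
}

# planted-truth selection world shared by test-selection.R and
# test-acceptance.R
planted_table <- function(seed, n = 140, n_inf = 8, n_noise = 50,
                          shift = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  feats <- list()
  # effect sizes spread from strong to borderline, echoing the reported
  # training-set p-value range of the selected features (1e-5 .. 2e-2)
  d <- seq(0.85, 0.40, length.out = n_inf) * shift
  for (i in seq_len(n_inf))
    feats[[paste0("inf", i)]] <- rnorm(n) + d[i] * y
  for (i in seq_len(n_noise))
    feats[[paste0("noise", i)]] <- rnorm(n)
  tab <- data.frame(case_id = sprintf("c%03d", 1:n),
                    label = ifelse(y == 1, "sarcoma", "leiomyoma"),
                    age = rnorm(n, 50, 10), stringsAsFactors = FALSE)
  for (nm in names(feats)) tab[[nm]] <- feats[[nm]]
  tab
}
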