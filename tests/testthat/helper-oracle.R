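# Naive, loop-based reference implementations of the 30 extended
# descriptors, written directly from their defining formulas and kept
# independent of the package's code paths. Inputs are plain data frames
# with columns x, y, pressure, pen_status, timestamp (ms).

oracle_strokes <- function(df) {
  # list of index vectors, one per maximal on-paper run
  strokes <- list()
  current <- integer()
  for (i in seq_len(nrow(df))) {
    if (df$pen_status[i] == 1) {
      current <- c(current, i)
    } else if (length(current) > 0) {
      strokes[[length(strokes) + 1]] <- current
      current <- integer()
    }
  }
  if (length(current) > 0) strokes[[length(strokes) + 1]] <- current
  strokes
}

oracle_sd <- function(v) {
  if (length(v) < 2) return(NA_real_)
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / (length(v) - 1))
}

oracle_directional <- function(df) {
  n <- nrow(df)
  angles <- numeric(0); slopes <- numeric(0); alts <- numeric(0)
  for (i in seq_len(n - 1)) {
    dx <- df$x[i + 1] - df$x[i]
    dy <- df$y[i + 1] - df$y[i]
    dz <- df$pressure[i + 1] - df$pressure[i]
    if (dx == 0) {
      angles <- c(angles, sign(dy) * 90)
    } else {
      angles <- c(angles, atan(dy / dx) * 180 / pi)
      slopes <- c(slopes, dy / dx)
    }
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    if (nrm > 0) alts <- c(alts, asin(dz / nrm) * 180 / pi)
  }
  c(MA = if (length(angles)) mean(angles) else NA_real_,
    MS = if (length(slopes)) mean(slopes) else NA_real_,
    Altitude = if (length(alts)) mean(alts) else NA_real_)
}

oracle_displacement <- function(df) {
  n <- nrow(df)
  td <- 0; hd <- 0; vd <- 0
  for (i in seq_len(n - 1)) {
    dx <- df$x[i + 1] - df$x[i]
    dy <- df$y[i + 1] - df$y[i]
    td <- td + sqrt(dx^2 + dy^2)
    hd <- hd + abs(dx)
    vd <- vd + abs(dy)
  }
  c(TD = td, HD = hd, VD = vd)
}

oracle_stroke_geometry <- function(df) {
  strokes <- oracle_strokes(df)
  S <- length(strokes)
  out <- c(MSH = NA_real_, MSW = NA_real_, MCD = NA_real_, MMDS = NA_real_,
           MSED = NA_real_, MVA = NA_real_, MHA = NA_real_)
  if (S == 0) return(out)
  msh <- c(); msw <- c()
  for (s in strokes) {
    after <- s[length(s)] + 1
    if (after <= nrow(df) && df$pen_status[after] == 0) {
      start <- s[1]
      msh <- c(msh, abs(df$y[after] - df$y[start]))
      msw <- c(msw, abs(df$x[after] - df$x[start]))
    }
  }
  if (length(msh)) {
    out["MSH"] <- mean(msh)
    out["MSW"] <- mean(msw)
  }
  if (S >= 2) {
    mcd <- c(); mmds <- c(); msed <- c(); mva <- c(); mha <- c()
    for (j in seq_len(S - 1)) {
      a <- strokes[[j]]; b <- strokes[[j + 1]]
      cxa <- mean(df$x[a]); cya <- mean(df$y[a])
      cxb <- mean(df$x[b]); cyb <- mean(df$y[b])
      mcd <- c(mcd, sqrt((cxb - cxa)^2 + (cyb - cya)^2))
      dmin <- Inf
      for (p in a) for (q in b) {
        d <- sqrt((df$x[q] - df$x[p])^2 + (df$y[q] - df$y[p])^2)
        if (d < dmin) dmin <- d
      }
      mmds <- c(mmds, dmin)
      ea <- a[length(a)]; sb <- b[1]
      msed <- c(msed, sqrt((df$x[ea] - df$x[sb])^2 + (df$y[ea] - df$y[sb])^2))
      eb <- b[length(b)]
      mva <- c(mva, abs(df$y[eb] - df$y[ea]))
      mha <- c(mha, abs(df$x[eb] - df$x[ea]))
    }
    out["MCD"] <- mean(mcd); out["MMDS"] <- mean(mmds)
    out["MSED"] <- mean(msed); out["MVA"] <- mean(mva); out["MHA"] <- mean(mha)
  }
  out
}

oracle_count_entropy <- function(values, alpha = NULL) {
  if (length(values) == 0) return(NA_real_)
  counts <- table(values)
  p <- as.numeric(counts) / length(values)
  if (is.null(alpha)) -sum(p * log2(p)) else log2(sum(p^alpha)) / (1 - alpha)
}

oracle_tke <- function(s) {
  n <- length(s)
  if (n < 3) return(NULL)
  psi <- numeric(n - 2)
  for (i in 2:(n - 1)) psi[i - 1] <- s[i]^2 - s[i - 1] * s[i + 1]
  psi
}

oracle_snr <- function(v) {
  if (is.null(v) || length(v) < 2) return(NA_real_)
  s <- oracle_sd(v)
  if (is.na(s) || s == 0) return(NA_real_)
  mean(v) / s
}

oracle_variability <- function(df) {
  n <- nrow(df)
  speeds <- c()
  for (i in seq_len(n - 1)) {
    dt <- (df$timestamp[i + 1] - df$timestamp[i]) / 1000
    if (dt > 0) {
      d <- sqrt((df$x[i + 1] - df$x[i])^2 + (df$y[i + 1] - df$y[i])^2)
      speeds <- c(speeds, d / dt)
    }
  }
  c(SSD = oracle_sd(speeds), PSD = oracle_sd(df$pressure))
}

# Independent first-IMF sifting: strict extrema with plateau runs
# collapsed to their first sample, outermost two extrema mirrored about
# the ends, natural-spline envelopes, SD < 0.2 Cauchy stop, 100 sifts.
oracle_find_extrema <- function(s) {
  n <- length(s)
  maxima <- integer(); minima <- integer()
  i <- 2
  while (i <= n - 1) {
    if (s[i] == s[i - 1]) { i <- i + 1; next }
    j <- i
    while (j < n && s[j + 1] == s[j]) j <- j + 1
    if (j >= n) break
    if (s[i] > s[i - 1] && s[i] > s[j + 1]) maxima <- c(maxima, i)
    if (s[i] < s[i - 1] && s[i] < s[j + 1]) minima <- c(minima, i)
    i <- j + 1
  }
  list(maxima = maxima, minima = minima)
}

oracle_envelope <- function(ext_idx, vals, n) {
  k <- length(ext_idx)
  take <- min(2, k)
  lt <- c(); lv <- c(); rt <- c(); rv <- c()
  for (m in seq_len(take)) {
    lt <- c(lt, 2 - ext_idx[m]); lv <- c(lv, vals[m])
    rt <- c(rt, 2 * n - ext_idx[k - m + 1]); rv <- c(rv, vals[k - m + 1])
  }
  tt <- c(lt, ext_idx, rt); vv <- c(lv, vals, rv)
  ord <- order(tt)
  tt <- tt[ord]; vv <- vv[ord]
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "natural")$y
}

oracle_imf1 <- function(s, sd_thr = 0.2, max_sift = 100) {
  n <- length(s)
  if (n < 4) return(NULL)
  h <- s
  for (it in seq_len(max_sift)) {
    ext <- oracle_find_extrema(h)
    if (length(ext$maxima) < 1 || length(ext$minima) < 1) {
      if (it == 1) return(NULL)
      break
    }
    up <- oracle_envelope(ext$maxima, h[ext$maxima], n)
    lo <- oracle_envelope(ext$minima, h[ext$minima], n)
    h_new <- h - (up + lo) / 2
    denom <- sum(h^2)
    crit <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (crit < sd_thr) break
  }
  h
}

oracle_hist_entropy <- function(v, bins = 64) {
  if (min(v) == max(v)) return(0)
  edges <- seq(min(v), max(v), length.out = bins + 1)
  counts <- numeric(bins)
  for (val in v) {
    b <- findInterval(val, edges, rightmost.closed = TRUE)
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

# The full 30-slot extended block.
oracle_extended_features <- function(df) {
  out <- c(
    oracle_directional(df)[c("MA", "MS")],
    oracle_displacement(df),
    oracle_stroke_geometry(df),
    HSE = oracle_count_entropy(df$x),
    VSE = oracle_count_entropy(df$y),
    HRE_2 = oracle_count_entropy(df$x, 2),
    HRE_3 = oracle_count_entropy(df$x, 3),
    VRE_2 = oracle_count_entropy(df$y, 2),
    VRE_3 = oracle_count_entropy(df$y, 3),
    CE_X = sum(df$x^2), CE_Y = sum(df$y^2),
    TKE_X = if (nrow(df) >= 3) sum(oracle_tke(df$x)) else NA_real_,
    TKE_Y = if (nrow(df) >= 3) sum(oracle_tke(df$y)) else NA_real_,
    SNRCE_X = oracle_snr(df$x^2), SNRCE_Y = oracle_snr(df$y^2),
    SNRTKE_X = oracle_snr(oracle_tke(df$x)),
    SNRTKE_Y = oracle_snr(oracle_tke(df$y)),
    oracle_variability(df),
    Altitude = oracle_directional(df)[["Altitude"]]
  )
  imf <- oracle_imf1(df$x)
  out["H_IMF1"] <- if (is.null(imf)) NA_real_ else oracle_hist_entropy(imf)
  out
}
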