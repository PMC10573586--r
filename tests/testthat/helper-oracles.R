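# Shared helpers and independent oracles. Oracles are deliberately naive
# (triple loops, O(n^2) scans) and never share code with the implementation
# they check.

# Noise/jitter-free effect configuration for deterministic geometry tests.
quiet_config <- function(...) {
  phantom_effect_config(variation_cv = 0, noise_sigma = 0,
                        vessel_probability = 0,
                        jitter_translation_mm = c(0, 0, 0),
                        jitter_rotation_deg = c(0, 0, 0), ...)
}

# Render a phantom, redrawing the jitter on clipping (mirrors the cohort
# generator's retry) so property tests over many seeds never abort.
render_with_retry <- function(class_label, cfg, seed) {
  for (attempt in 0:49) {
    p <- sample_phantom_params(class_label, cfg, seed + attempt * 10007)
    r <- tryCatch(render_phantom(p), error = function(e) NULL)
    if (!is.null(r)) return(list(params = p, patch = r$patch, mask = r$mask))
  }
  stop("render_with_retry: no non-clipping draw found")
}

# Brute-force confusion counting (independent of confusion_at_threshold).
oracle_confusion <- function(scores, labels, threshold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(scores)) {
    pos <- scores[i] >= threshold
    if (labels[i] == 1 && pos) tp <- tp + 1
    if (labels[i] == 0 && pos) fp <- fp + 1
    if (labels[i] == 1 && !pos) fn <- fn + 1
    if (labels[i] == 0 && !pos) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# O(n^2) pairwise Mann-Whitney AUROC (ties count one half).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every candidate threshold that produces a
# distinct confusion matrix (all midpoints between adjacent distinct
# scores, the scores themselves, and +/-Inf); returns the best achievable J.
oracle_best_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(-Inf, s, s[-1] - diff(s) / 2, Inf)
  best <- -Inf
  for (t in cands) {
    cc <- oracle_confusion(scores, labels, t)
    j <- cc["tp"] / (cc["tp"] + cc["fn"]) - cc["fp"] / (cc["fp"] + cc["tn"])
    best <- max(best, j)
  }
  unname(best)
}

# Triple-loop patch extraction with zero padding (voxel-index arithmetic
# only; checks extract_patch on unit-grid volumes).
oracle_extract <- function(vox, center_vox0, dims) {
  out <- array(0, dims)
  start0 <- center_vox0 - dims %/% 2
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      src <- start0 + c(i, j, k) # 1-based source index
      if (all(src >= 1) && all(src <= dim(vox))) {
        out[i, j, k] <- vox[src[1], src[2], src[3]]
      }
    }
  out
}

# Direct 3-D convolution by summation (zero padding), independent of the
# im2col implementation. X: (d1,d2,d3,Cin); W: (Cout, k^3*Cin) with kernel
# offsets fastest, channels slowest (the engine's layout).
oracle_conv3d <- function(X, W, b, k, stride, pad) {
  d <- dim(X)[1:3]; cin <- dim(X)[4]; cout <- nrow(W)
  od <- (d + 2 * pad - k) %/% stride + 1
  out <- array(0, c(od, cout))
  for (oc in seq_len(cout)) for (ox in seq_len(od[1]))
    for (oy in seq_len(od[2])) for (oz in seq_len(od[3])) {
      acc <- b[oc]
      col <- 0
      for (ic in seq_len(cin)) for (dz in 0:(k - 1)) for (dy in 0:(k - 1))
        for (dx in 0:(k - 1)) {
          # W columns: expand.grid(dx, dy, dz, c) order
          col <- (ic - 1) * k^3 + dz * k^2 + dy * k + dx + 1
          sx <- (ox - 1) * stride + dx - pad + 1
          sy <- (oy - 1) * stride + dy - pad + 1
          sz <- (oz - 1) * stride + dz - pad + 1
          if (sx >= 1 && sx <= d[1] && sy >= 1 && sy <= d[2] &&
              sz >= 1 && sz <= d[3]) {
            acc <- acc + W[oc, col] * X[sx, sy, sz, ic]
          }
        }
      out[ox, oy, oz, oc] <- acc
    }
  out
}

random_patch <- function(seed = 1) {
  set.seed(seed)
  array(runif(prod(patch_geometry()$dims)), dim = patch_geometry()$dims)
}
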