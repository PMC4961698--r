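# Independent brute-force voting oracle: a literal transliteration of the
# weighted-label-fusion equations as nested R loops. Shares no code with the
# package kernel; deliberately slow and only usable on tiny instances.

oracle_patch_vals <- function(img, ctr, r) {
  d <- dim(img)
  vals <- c()
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    x <- ctr[1] + dx; y <- ctr[2] + dy; z <- ctr[3] + dz
    vals <- c(vals, if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2] &&
                        z >= 1 && z <= d[3]) img[x, y, z] else NA_real_)
  }
  vals
}

oracle_ss <- function(a, b) {
  av <- a[is.finite(a)]; bv <- b[is.finite(b)]
  m1 <- mean(av); m2 <- mean(bv)
  s1 <- sqrt(mean((av - m1)^2)); s2 <- sqrt(mean((bv - m2)^2))
  lum <- if (m1^2 + m2^2 < 1e-12) 1 else 2 * m1 * m2 / (m1^2 + m2^2)
  if (s1 < 1e-12 && s2 < 1e-12) return(if (abs(m1 - m2) < 1e-12) 1 else lum)
  con <- if (s1^2 + s2^2 < 1e-12) 1 else 2 * s1 * s2 / (s1^2 + s2^2)
  lum * con
}

oracle_ssd <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  sum((a[ok] - b[ok])^2) * length(a) / sum(ok)
}

# returns 4D vote array (grid x labels) normalized per voxel, labels sorted
oracle_vote <- function(subj, tmpl_int, tmpl_lab, mask, patch_r, search_r,
                        block_r, lambda, eps, sigma_d, th, vox = c(1, 1, 1),
                        normalize_blocks = FALSE) {
  d <- dim(subj)
  labels <- sort(unique(unlist(lapply(tmpl_lab, as.vector))))
  K <- length(labels)
  votes <- array(0, c(d, K))
  for (zi in 1:d[3]) for (yi in 1:d[2]) for (xi in 1:d[1]) {
    if (!mask[xi, yi, zi]) next
    ctr <- c(xi, yi, zi)
    p <- oracle_patch_vals(subj, ctr, patch_r)
    cand <- list()
    for (s in seq_along(tmpl_int)) {
      for (dz in -search_r:search_r) for (dy in -search_r:search_r)
        for (dx in -search_r:search_r) {
          j <- ctr + c(dx, dy, dz)
          if (any(j < 1) || any(j > d)) next
          q <- oracle_patch_vals(tmpl_int[[s]], j, patch_r)
          cand[[length(cand) + 1]] <- list(
            s = s, j = j, ssd = oracle_ssd(p, q),
            d2 = sum((c(dx, dy, dz) * vox)^2),
            elig = oracle_ss(p, q) > th)
        }
    }
    if (length(cand) == 0) next
    h2 <- lambda * min(vapply(cand, function(c) c$ssd, 0)) + eps
    ws <- vapply(cand, function(c)
      if (c$elig) exp(-c$d2 / (2 * sigma_d^2)) * exp(-c$ssd / h2) else 0, 0)
    W <- sum(ws)
    if (W <= 0) {
      obs <- sort(unique(vapply(cand, function(c)
        tmpl_lab[[c$s]][c$j[1], c$j[2], c$j[3]], 0L)))
      for (l in obs) votes[xi, yi, zi, match(l, labels)] <-
          votes[xi, yi, zi, match(l, labels)] + 1 / length(obs)
      next
    }
    for (ci in seq_along(cand)) {
      w <- ws[ci]
      if (w <= 0) next
      if (normalize_blocks) w <- w / W
      cc <- cand[[ci]]
      for (dz in -block_r:block_r) for (dy in -block_r:block_r)
        for (dx in -block_r:block_r) {
          a <- ctr + c(dx, dy, dz); b <- cc$j + c(dx, dy, dz)
          if (any(a < 1) || any(a > d) || any(b < 1) || any(b > d)) next
          l <- tmpl_lab[[cc$s]][b[1], b[2], b[3]]
          k <- match(l, labels)
          votes[a[1], a[2], a[3], k] <- votes[a[1], a[2], a[3], k] + w
        }
    }
  }
  for (zi in 1:d[3]) for (yi in 1:d[2]) for (xi in 1:d[1]) {
    tot <- sum(votes[xi, yi, zi, ])
    if (tot > 0) votes[xi, yi, zi, ] <- votes[xi, yi, zi, ] / tot
  }
  list(votes = votes, labels = labels)
}
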