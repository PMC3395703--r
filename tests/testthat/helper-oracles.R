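# Independent brute-force oracles used to freeze expected values.

# 3'-trim oracle: scan every window start directly.
oracle_trim_length <- function(q, window, threshold) {
  n <- length(q)
  if (n == 0) return(0L)
  if (n <= window) return(if (mean(q) >= threshold) n else 0L)
  last <- 0L
  for (i in 1:(n - window + 1)) {
    if (mean(q[i:(i + window - 1)]) >= threshold) last <- i
  }
  if (last == 0L) 0L else min(last + window - 1L, n)
}

# Ungapped overlap oracle: best identity over every relative offset with
# overlap >= minOverlap (valid for substitution-only fixtures).
oracle_best_overlap <- function(a, b, minOverlap = 1L) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- list(overlap = 0L, identity = 0)
  for (off in (-nb + 1):(na - 1)) {
    ia <- max(1, 1 + off):min(na, nb + off)
    ib <- ia - off
    ov <- length(ia)
    if (ov < minOverlap) next
    id <- mean(ca[ia] == cb[ib])
    if (ov > best$overlap && id > best$identity ||
        id > best$identity ||
        (id == best$identity && ov > best$overlap)) {
      best <- list(overlap = ov, identity = id)
    }
  }
  best
}

# Digest oracle: check every position for a site occurrence, no regex.
oracle_digest <- function(sequence, site = "CCGG", cutOffset = 1L) {
  n <- nchar(sequence); w <- nchar(site)
  cuts <- integer()
  for (i in 1:(n - w + 1)) {
    if (substr(sequence, i, i + w - 1) == site) cuts <- c(cuts, i - 1L + cutOffset)
  }
  cuts <- cuts[cuts >= 1]
  if (!length(cuts)) n else cuts
}

# Hand OLS oracle.
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r2 = 1 - ss_res / ss_tot)
}

# Exhaustive overlap-graph oracle: connected components of the pairwise
# "would assemble" graph at the given thresholds.
oracle_overlap_components <- function(seqs, minOverlap = 50L, minIdentity = 0.98) {
  n <- length(seqs)
  adj <- diag(n) == 1
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ov <- overlapIdentity(seqs[i], seqs[j])
      adj[i, j] <- adj[j, i] <-
        ov$overlap >= minOverlap && ov$identity >= minIdentity
    }
  }
  comp <- seq_len(n)
  repeat {
    new_comp <- sapply(seq_len(n), function(i) min(comp[adj[i, ]]))
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  match(comp, unique(comp))
}

# Naive agglomerative complete-linkage oracle cut at height h.
oracle_complete_linkage <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

# Substitute exactly k positions of a DNA string (never to the same base).
mutate_positions <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}
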