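# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most literal method available and share no code with the
# package implementations they check.

# NX/LX/auN by an explicit cumulative scan over the sorted length list
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= total * x / 100) return(c(n = s[i], l = i))
  }
}

oracle_aun <- function(lengths) {
  total <- sum(as.numeric(lengths))
  val <- sum(as.numeric(lengths)^2) / total
  floor(val + 0.5)
}

# per-window DUST score by full recount of every window (triplet strings
# matched against the explicit 64-triplet alphabet, recounted per window)
oracle_dust <- function(seq, window = 64L, threshold = 20) {
  L <- nchar(seq)
  if (L < 3L) return(data.frame(start = integer(), end = integer()))
  alphabet64 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
  trips <- substring(seq, 1:(L - 2L), 3:L)
  codes <- match(trips, alphabet64)           # NA for triplets containing N
  w <- min(window, L)
  tw <- w - 2L
  masked <- rep(FALSE, L)
  for (i in 1:(L - w + 1L)) {
    cnt <- tabulate(codes[i:(i + tw - 1L)], 64L)
    s <- 10 * sum(cnt * (cnt - 1) / 2) / tw
    if (s > threshold) masked[i:(i + w - 1L)] <- TRUE
  }
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# six-frame complete-ORF scan written against the same definition (first
# in-frame ATG after the previous stop, through the next stop), but by
# literal string chopping
oracle_orfs <- function(seq, min_aa = 100L) {
  rc <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(seq)
  rows <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else rc(seq)
    for (f in 0:2) {
      i <- f + 1L
      orf_start <- NA
      prev_was_stop_boundary <- TRUE
      searching_atg <- TRUE
      while (i + 2L <= L) {
        cod <- substr(s, i, i + 2L)
        if (searching_atg && cod == "ATG") {
          orf_start <- i
          searching_atg <- FALSE
        }
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(orf_start) && (i - orf_start) / 3 >= min_aa) {
            a <- orf_start - 1L
            b <- i + 2L
            if (str == "-") { t <- a; a <- L - b; b <- L - t }
            rows[[length(rows) + 1L]] <-
              data.frame(start = a, end = b, strand = str, frame = f)
          }
          orf_start <- NA
          searching_atg <- TRUE
        }
        i <- i + 3L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base depth by literal interval stabbing
oracle_pair_depth <- function(pairs, contig_len, max_insert = 1000L) {
  depth <- integer(contig_len)
  for (i in seq_len(nrow(pairs))) {
    lo <- min(pairs$r1_start[i], pairs$r2_start[i])
    hi <- max(pairs$r1_end[i], pairs$r2_end[i])
    left <- if (pairs$r1_start[i] <= pairs$r2_start[i])
      pairs$r1_strand[i] else pairs$r2_strand[i]
    right <- if (pairs$r1_start[i] <= pairs$r2_start[i])
      pairs$r2_strand[i] else pairs$r1_strand[i]
    if (left == "+" && right == "-" && (hi - lo) <= max_insert) {
      for (p in (lo + 1L):hi) depth[p] <- depth[p] + 1L
    }
  }
  depth
}

# connected components by union-find
oracle_components <- function(edges, vertices) {
  parent <- setNames(vertices, vertices)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[[1]][i]); rb <- find(edges[[2]][i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(vertices, find, character(1))
  unname(lapply(split(vertices, roots), sort))
}

# monotone-run chaining by a literal scan (no shared code with the greedy
# implementation's bookkeeping); returns index groups in pos_a order
oracle_chain <- function(pos_a, pos_b, max_gap = 1e6) {
  ord <- order(pos_a)
  a <- pos_a[ord]; b <- pos_b[ord]
  n <- length(a)
  if (n == 0L) return(list())
  groups <- list(ord[1])
  cur_dir <- NA
  if (n > 1L) for (i in 2:n) {
    step <- b[i] - b[i - 1L]
    ok_gap <- (a[i] - a[i - 1L]) <= max_gap && abs(step) <= max_gap
    ok_dir <- is.na(cur_dir) || sign(step) == 0 || sign(step) == cur_dir
    if (ok_gap && ok_dir) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], ord[i])
      if (is.na(cur_dir) && sign(step) != 0) cur_dir <- sign(step)
    } else {
      groups[[length(groups) + 1L]] <- ord[i]
      cur_dir <- NA
    }
  }
  groups
}

# closed-form simple OLS on log10 scale
oracle_ols_log10 <- function(len_a, len_b) {
  x <- log10(len_a); y <- log10(len_b)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, r2 = r2)
}

iv_width_test <- function(df) sum(df$end - df$start)

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
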