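# Independent oracles and small fixture builders shared across tests.

# Naive UPGMA: average linkage computed every step as the mean over ALL
# cross pairs of the ORIGINAL distance matrix (no Lance-Williams update),
# with the same lexicographic tie-break. Returns merge heights (sorted)
# and the set of clade keys.
naive_upgma <- function(dm) {
  labs <- rownames(dm)
  clusters <- lapply(labs, identity)
  heights <- numeric(0)
  clades <- character(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        link <- mean(dm[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(link = link, i = i, j = j, lab = lab)
        if (is.null(best) || link < best$link ||
            (link == best$link && (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    heights <- c(heights, best$link / 2)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    clades <- c(clades, paste(sort(merged), collapse = "\r"))
  }
  list(heights = sort(heights), clades = sort(clades))
}

# Literal four-branch transcription of the verbal band-calling rule.
verbal_score_band <- function(i1, i2, t_high = 100, t_low = 50) {
  if (i1 >= t_high && i2 >= t_high) return(1L)                  # both confident
  if (i1 >= t_high && i2 >= t_low) return(1L)                   # disagreement, one high one ok
  if (i2 >= t_high && i1 >= t_low) return(1L)
  0L                                                            # both below high, or one below low
}

random_binary_matrix <- function(n, L, p = 0.5) {
  m <- matrix(rbinom(n * L, 1L, p), n, L,
              dimnames = list(sprintf("I%02d", seq_len(n)), sprintf("L%02d", seq_len(L))))
  m
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(sum(upper.tri(d)), 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

make_intensity_df <- function(isolates, loci, fill = 800, plate = "P1") {
  expand <- expand.grid(isolate_id = isolates, replicate = 1:2, locus_id = loci,
                        stringsAsFactors = FALSE)
  data.frame(isolate_id = expand$isolate_id, replicate = expand$replicate,
             plate_id = plate, locus_id = expand$locus_id, intensity = fill,
             stringsAsFactors = FALSE)
}

# set intensities for one isolate/locus pair (both replicates)
set_intensity <- function(df, isolate, locus, i1, i2) {
  df$intensity[df$isolate_id == isolate & df$locus_id == locus & df$replicate == 1] <- i1
  df$intensity[df$isolate_id == isolate & df$locus_id == locus & df$replicate == 2] <- i2
  df
}

clade_key <- function(x) paste(sort(x), collapse = "\r")
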