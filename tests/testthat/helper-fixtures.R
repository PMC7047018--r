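# Small synthetic datasets shared across test files. Built once per test
# run; sizes chosen so the whole suite stays fast.

fast_defect_config <- function(seed = 3L) {
  sim_config(
    n_genes = 12L, root_cds_codons = 120L, expression_dropout = 0,
    isoform_mean = 3, truncation_prob = 0.2,
    defect_rates = c(internal_stop_reference = 0.2,
                     no_stop_six_frames = 0.2,
                     missing_annotation = 0.2),
    seed = seed)
}

clean_config <- function(n_genes = 10L, seed = 5L, root_cds_codons = 120L,
                         ...) {
  sim_config(
    n_genes = n_genes, root_cds_codons = root_cds_codons,
    expression_dropout = 0,
    isoform_mean = 3, truncation_prob = 0.2,
    defect_rates = c(internal_stop_reference = 0, no_stop_six_frames = 0,
                     missing_annotation = 0),
    seed = seed, ...)
}

## Brute-force ORF oracle: enumerate every stop-terminated in-frame segment
## over the three forward frames and return the longest (5'-most, lowest
## frame on ties) as c(start0, len, frame), or NULL.
orf_oracle <- function(seq) {
  seq <- toupper(seq)
  best <- NULL
  for (f in 0:2) {
    n <- nchar(seq)
    starts <- if (n - f >= 3) seq.int(f + 1L, n - 2L, by = 3L) else integer(0)
    codons <- substring(seq, starts, starts + 2L)
    prev_stop <- 0L # codon index of previous stop
    for (i in seq_along(codons)) {
      if (codons[i] %in% c("TAA", "TAG", "TGA")) {
        seg_start0 <- f + prev_stop * 3L
        len <- (i - prev_stop) * 3L
        if (is.null(best) || len > best[2] ||
            (len == best[2] && seg_start0 < best[1])) {
          best <- c(seg_start0, len, f)
        }
        prev_stop <- i
      }
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Least-squares quartet oracle: fit each of the 3 unrooted quartet
## topologies to a distance matrix by non-negative least squares over the
## 5 branch lengths and return the winning split as a sorted pair-string,
## e.g. "AB|CD".
quartet_oracle <- function(d, taxa = rownames(d)) {
  splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (s in splits) {
    p1 <- s[1]; p2 <- s[2]; q1 <- s[3]; q2 <- s[4]
    ## path matrix rows: the 6 taxon pairs; columns: 4 terminal branches
    ## plus the internal branch of this split
    pairs <- rbind(c(p1, p2), c(p1, q1), c(p1, q2),
                   c(p2, q1), c(p2, q2), c(q1, q2))
    X <- matrix(0, 6, 5)
    for (r in 1:6) {
      X[r, pairs[r, 1]] <- 1
      X[r, pairs[r, 2]] <- 1
      same_side <- all(pairs[r, ] %in% c(p1, p2)) ||
        all(pairs[r, ] %in% c(q1, q2))
      if (!same_side) X[r, 5] <- 1
    }
    y <- apply(pairs, 1, function(p) d[p[1], p[2]])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss,
                   split = paste(sort(c(
                     paste(sort(taxa[c(p1, p2)]), collapse = ""),
                     paste(sort(taxa[c(q1, q2)]), collapse = ""))),
                     collapse = "|"))
    }
  }
  best$split
}

## The split of a 4-taxon unrooted tree in the same pair-string form.
quartet_split <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  sizes <- lengths(pp)
  k <- which(sizes == 2)[1]
  pair <- sort(tree$tip.label[pp[[k]]])
  rest <- sort(setdiff(tree$tip.label, pair))
  paste(sort(c(paste(pair, collapse = ""), paste(rest, collapse = ""))),
        collapse = "|")
}
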