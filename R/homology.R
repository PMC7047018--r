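## Unique k-mers of a sequence with their first-occurrence positions
## (1-based); k = 12 mirrors a match12 seed.
seq_kmers <- function(seq, k = 12L) {
  n <- nchar(seq)
  if (n < k) return(list(kmer = character(0), pos = integer(0)))
  all <- substring(seq, 1:(n - k + 1L), k:n)
  keep <- !duplicated(all)
  list(kmer = all[keep], pos = which(keep))
}

## For each query, the subjects sharing >= min_shared exact k-mers, with
## the shared-word count and the median seed diagonal (query position -
## subject position), which centres the banded alignment.
seed_candidates <- function(queries, subjects, k = 12L, min_shared = 2L) {
  sk <- lapply(subjects, seq_kmers, k = k)
  kmers <- unlist(lapply(sk, `[[`, "kmer"), use.names = FALSE)
  dict <- unique(kmers)
  ids <- factor(match(kmers, dict), levels = seq_along(dict))
  post_j <- split(rep.int(seq_along(sk),
                          lengths(lapply(sk, `[[`, "kmer"))), ids)
  post_p <- split(unlist(lapply(sk, `[[`, "pos"), use.names = FALSE), ids)
  lapply(queries, function(q) {
    qk <- seq_kmers(q, k)
    qi <- match(qk$kmer, dict)
    ok <- !is.na(qi)
    if (!any(ok)) {
      return(list(j = integer(0), count = integer(0), diag = integer(0)))
    }
    hit_ids <- qi[ok]
    lens <- lengths(post_j[hit_ids])
    subj <- unlist(post_j[hit_ids], use.names = FALSE)
    spos <- unlist(post_p[hit_ids], use.names = FALSE)
    qpos <- rep.int(qk$pos[ok], lens)
    tab <- tabulate(subj, nbins = length(subjects))
    sel <- which(tab >= min_shared)
    diag <- vapply(sel, function(s) {
      as.integer(stats::median(qpos[subj == s] - spos[subj == s]))
    }, integer(1))
    list(j = sel, count = tab[sel], diag = diag)
  })
}

#' Thresholded pairwise similarity search
#'
#' Local (affine-gap) alignment of every query against every subject,
#' keeping hits that meet both an identity and a query-coverage threshold
#' (defaults 70% identity, 50% coverage — the orthology-search operating
#' point). Scoring: match +1, mismatch -1, gap open -2, gap extend -1;
#' ambiguity codes score 0. Candidate pairs are seeded by exact 12-mer
#' matches (`min_shared_kmers` shared words required) before full
#' alignment; set `seed_filter = FALSE` for an exhaustive scan.
#'
#' Identity is matches / aligned columns (gap columns included); coverage
#' is aligned query bases / query length. Reported spans are 0-based,
#' half-open.
#'
#' @param queries,subjects Named character vectors of DNA sequences.
#' @param min_identity,min_coverage Inclusion thresholds in `[0,1]`.
#' @param seed_filter Use the 12-mer seed prefilter (default `TRUE`).
#' @param min_shared_kmers Shared 12-mers required to align a pair.
#' @return data.frame with columns `query_id`, `subject_id`, `score`,
#'   `identity`, `coverage`, `qstart`, `qend`, `sstart`, `send`.
#' @export
similarity_search <- function(queries, subjects,
                              min_identity = 0.70, min_coverage = 0.50,
                              seed_filter = TRUE, min_shared_kmers = 3L) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), qstart = integer(0),
                      qend = integer(0), sstart = integer(0),
                      send = integer(0), stringsAsFactors = FALSE)
  if (length(queries) == 0L || length(subjects) == 0L) return(empty)
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  cand <- if (seed_filter) {
    seed_candidates(queries, subjects, min_shared = min_shared_kmers)
  } else {
    rep(list(list(j = seq_along(subjects))), length(queries))
  }
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    js <- cand[[i]]$j
    if (length(js) == 0L) next
    qlen <- nchar(queries[[i]])
    got <- vector("list", length(js))
    for (jj in seq_along(js)) {
      j <- js[jj]
      a <- .sw_align(queries[[i]], subjects[[j]])
      if (a$columns == 0) next
      ident <- a$matches / a$columns
      cov <- (a$qend - a$qstart) / qlen
      if (ident >= min_identity && cov >= min_coverage) {
        got[[jj]] <- data.frame(
          query_id = names(queries)[i], subject_id = names(subjects)[j],
          score = a$score, identity = ident, coverage = cov,
          qstart = a$qstart, qend = a$qend,
          sstart = a$sstart, send = a$send,
          stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- do.call(rbind, got)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

## Both-direction thresholded search over one set of candidate pairs: each
## unordered pair is aligned once (score, identity and spans are direction
## symmetric; only the coverage denominator differs), yielding the a-to-b
## and b-to-a hit tables the RBH step needs at half the alignment cost.
similarity_search_both <- function(set_a, set_b,
                                   min_identity = 0.70, min_coverage = 0.50,
                                   min_shared_kmers = 3L,
                                   band_width = 150L) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), qstart = integer(0),
                      qend = integer(0), sstart = integer(0),
                      send = integer(0), stringsAsFactors = FALSE)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    return(list(ab = empty, ba = empty))
  }
  cand <- seed_candidates(set_a, set_b, min_shared = min_shared_kmers)
  ab <- list()
  ba <- list()
  for (i in seq_along(set_a)) {
    for (jj in seq_along(cand[[i]]$j)) {
      j <- cand[[i]]$j[jj]
      a <- .sw_align(set_a[[i]], set_b[[j]],
                     band_diag = cand[[i]]$diag[jj],
                     band_width = band_width)
      if (a$columns == 0) next
      ident <- a$matches / a$columns
      if (ident < min_identity) next
      cov_a <- (a$qend - a$qstart) / nchar(set_a[[i]])
      cov_b <- (a$send - a$sstart) / nchar(set_b[[j]])
      if (cov_a >= min_coverage) {
        ab[[length(ab) + 1L]] <- data.frame(
          query_id = names(set_a)[i], subject_id = names(set_b)[j],
          score = a$score, identity = ident, coverage = cov_a,
          qstart = a$qstart, qend = a$qend, sstart = a$sstart,
          send = a$send, stringsAsFactors = FALSE)
      }
      if (cov_b >= min_coverage) {
        ba[[length(ba) + 1L]] <- data.frame(
          query_id = names(set_b)[j], subject_id = names(set_a)[i],
          score = a$score, identity = ident, coverage = cov_b,
          qstart = a$sstart, qend = a$send, sstart = a$qstart,
          send = a$qend, stringsAsFactors = FALSE)
      }
    }
  }
  list(ab = if (length(ab)) do.call(rbind, ab) else empty,
       ba = if (length(ba)) do.call(rbind, ba) else empty)
}

## Per query, the top-scoring subject. Exact score ties are generic when
## the subject set carries redundant isoforms, so ties are broken
## deterministically: identity, then coverage, then lexicographically
## smallest subject id. Reciprocity (both directions must agree) remains
## the guard against arbitrary orthology.
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  out <- character(0)
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, ]
    h <- h[order(-h$score, -h$identity, -h$coverage, h$subject_id), ]
    out[q] <- h$subject_id[1]
  }
  out
}

#' Reciprocal best hits
#'
#' A pair (a, b) is kept iff b is a's top-scoring subject in the a-to-b
#' search and a is b's top-scoring subject in the b-to-a search, with ties
#' broken deterministically (identity, coverage, subject id); the
#' reciprocity requirement itself guards against ambiguous orthology.
#'
#' @param hits_ab,hits_ba Hit tables from [similarity_search()] run in the
#'   two directions with identical thresholds.
#' @return data.frame with columns `query_id` (a-side), `subject_id`
#'   (b-side), `score` (a-to-b score).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  ab <- best_hits(hits_ab)
  ba <- best_hits(hits_ba)
  keep <- names(ab)[vapply(names(ab), function(a) {
    b <- ab[[a]]
    !is.na(ba[b]) && identical(unname(ba[b]), a)
  }, logical(1))]
  if (length(keep) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  sc <- vapply(keep, function(a) {
    h <- hits_ab[hits_ab$query_id == a & hits_ab$subject_id == ab[[a]], ]
    max(h$score)
  }, numeric(1))
  data.frame(query_id = keep, subject_id = unname(ab[keep]),
             score = unname(sc), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select one representative transcript per reference gene
#'
#' Several transcripts (isoforms) of a target species can pair with the
#' same reference gene; downstream analysis uses a single representative:
#' highest RBH score, ties broken by longer CDS, then by lexicographically
#' smallest transcript id.
#'
#' @param rbh RBH table from [reciprocal_best_hits()] (query = transcript,
#'   subject = reference gene).
#' @param cds_lengths Named numeric vector of CDS lengths per transcript.
#' @return Named character vector: reference gene id -> transcript id.
#' @export
select_representative <- function(rbh, cds_lengths) {
  if (nrow(rbh) == 0L) return(stats::setNames(character(0), character(0)))
  missing <- setdiff(rbh$query_id, names(cds_lengths))
  if (length(missing)) stop("no CDS length for: ", missing[1])
  out <- character(0)
  for (g in unique(rbh$subject_id)) {
    h <- rbh[rbh$subject_id == g, ]
    h <- h[order(-h$score, -cds_lengths[h$query_id], h$query_id), ]
    out[g] <- h$query_id[1]
  }
  out
}

#' Compare annotation lengths across paired sequence sets
#'
#' For equivalent sequence pairs (for instance reciprocal best hits between
#' a long-read transcript set and a reference annotation), counts how many
#' pairs have the first sequence strictly longer than the second.
#'
#' @param pairs data.frame/matrix whose first two columns are ids in set A
#'   and set B.
#' @param lengths_a,lengths_b Named numeric vectors of sequence lengths.
#' @return Named integer vector `c(n_longer =, n_other =)`;
#'   `n_longer + n_other == nrow(pairs)`.
#' @export
compare_annotation_lengths <- function(pairs, lengths_a, lengths_b) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) return(c(n_longer = 0L, n_other = 0L))
  la <- lengths_a[as.character(pairs[[1]])]
  lb <- lengths_b[as.character(pairs[[2]])]
  if (anyNA(la) || anyNA(lb)) stop("missing length for a paired id")
  c(n_longer = sum(la > lb), n_other = sum(la <= lb))
}
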