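split_cell <- function(cell) {
  if (is.na(cell) || cell == "." || cell == "") character(0)
  else strsplit(cell, ",", fixed = TRUE)[[1]]
}

#' Build transitive ortholog groups
#'
#' One group per syntenic-ortholog table row. Orthology is transitive: a
#' target-species transcript paired (by reciprocal best hit) with the
#' anchor reference gene of a row is orthologous to every syntenic gene in
#' that row. Each target species contributes at most its single
#' representative transcript. The group's category counts the target
#' species with a representative (0-3); WGD retention per duplicated
#' lineage is `retained` iff the row holds two gene ids for that lineage.
#'
#' @param synteny data.frame from [read_synteny()].
#' @param rbh_maps Named list (per target species) of named character
#'   vectors: anchor gene id -> representative transcript id, as returned
#'   by [select_representative()].
#' @param anchor Anchor reference species column name (default
#'   [anchor_species()]).
#' @param lineages WGD lineage column names (default [wgd_lineages()]).
#' @return List of `ortho_group` lists (fields `group_id`, `members`,
#'   `category`, `retention`), classed `ortho_groups`. Rows whose anchor
#'   cell is missing are skipped with a warning.
#' @export
build_groups <- function(synteny, rbh_maps, anchor = anchor_species(),
                         lineages = wgd_lineages()) {
  stopifnot(anchor %in% names(synteny))
  ref_cols <- setdiff(names(synteny), "group_id")
  groups <- list()
  skipped <- 0L
  for (r in seq_len(nrow(synteny))) {
    anchor_ids <- split_cell(synteny[[anchor]][r])
    if (length(anchor_ids) == 0L) {
      skipped <- skipped + 1L
      next
    }
    members <- lapply(ref_cols, function(sp) split_cell(synteny[[sp]][r]))
    names(members) <- ref_cols
    for (sp in names(rbh_maps)) {
      hit <- unlist(rbh_maps[[sp]][anchor_ids], use.names = FALSE)
      members[[sp]] <- unname(hit[!is.na(hit)])
    }
    category <- sum(vapply(names(rbh_maps),
                           function(sp) length(members[[sp]]) > 0L,
                           logical(1)))
    retention <- stats::setNames(
      ifelse(vapply(lineages, function(sp) length(members[[sp]]) == 2L,
                    logical(1)),
             "retained", "fractionated"),
      lineages)
    groups[[length(groups) + 1L]] <- list(
      group_id = synteny$group_id[r] %||% as.character(r),
      members = members, category = category, retention = retention)
  }
  if (skipped > 0L) {
    warning(skipped, " synteny row(s) without an anchor gene were skipped")
  }
  structure(groups, class = "ortho_groups")
}

#' Tally ortholog groups by representation category
#'
#' @param groups `ortho_groups` from [build_groups()].
#' @return Named integer vector of counts for categories 0, 1, 2, 3
#'   (number of target species holding a representative transcript);
#'   sums to `length(groups)`.
#' @export
tally_categories <- function(groups) {
  cats <- vapply(groups, function(g) g$category, numeric(1))
  out <- vapply(0:3, function(k) sum(cats == k), integer(1))
  stats::setNames(out, as.character(0:3))
}

#' Screen a named gene list against the ortholog groups
#'
#' Reports, for each queried anchor gene id, whether it sits in the
#' syntenic table and which target species hold a representative
#' transcript for its group.
#'
#' @param groups `ortho_groups` from [build_groups()].
#' @param anchor_gene_ids Character vector of anchor gene ids.
#' @param anchor Anchor species label.
#' @return data.frame with `gene_id`, `in_synteny`, one logical column per
#'   target species, and `category` (NA when not in synteny).
#' @export
screen_gene_list <- function(groups, anchor_gene_ids,
                             anchor = anchor_species()) {
  targets <- target_species()
  anchor_index <- lapply(groups, function(g) g$members[[anchor]])
  rows <- lapply(anchor_gene_ids, function(id) {
    hit <- which(vapply(anchor_index, function(ids) id %in% ids, logical(1)))
    if (length(hit) == 0L) {
      pres <- stats::setNames(rep(FALSE, length(targets)), targets)
      return(data.frame(gene_id = id, in_synteny = FALSE, t(pres),
                        category = NA_integer_, stringsAsFactors = FALSE))
    }
    g <- groups[[hit[1]]]
    pres <- stats::setNames(
      vapply(targets, function(sp) length(g$members[[sp]]) > 0L,
             logical(1)), targets)
    data.frame(gene_id = id, in_synteny = TRUE, t(pres),
               category = g$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ortho_groups <- function(x, ...) {
  tal <- tally_categories(x)
  cat(sprintf(
    "<ortho_groups> %d groups; category 0/1/2/3 = %s\n",
    length(x), paste(tal, collapse = "/")))
  invisible(x)
}
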