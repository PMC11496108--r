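# Scoring genome-scale-model reactions from gene-level differential-
# expression z-scores: pooled reaction z = sum of associated gene z-scores,
# reactions with identical gene sets deduplicated to one representative,
# significance at pooled z strictly greater than 3.

#' Load reaction-gene associations from an SBML file
#'
#' Supports SBML Level 3 `fbc:geneProductAssociation` elements (all
#' referenced gene products are collected, regardless of and/or structure,
#' since pooling sums over the full associated gene set) and Level 2 notes
#' containing `GENE_ASSOCIATION:` strings.
#'
#' @param path Path to an SBML file.
#' @return Named list mapping reaction id to a character vector of gene ids
#'   (deduplicated); reactions without genes map to `character(0)` and are
#'   excluded from scoring downstream. Attribute `n_unparsed` counts
#'   reactions whose association could not be parsed (flagged with a
#'   warning, not an error).
#' @export
load_gene_associations <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  rxns <- xml2::xml_find_all(doc, ".//*[local-name() = 'reaction']")
  out <- list()
  n_unparsed <- 0L
  # map fbc:id -> fbc:label if gene products are declared
  gp <- xml2::xml_find_all(doc, ".//*[local-name() = 'geneProduct']")
  gp_map <- character(0)
  if (length(gp) > 0) {
    gid <- xml2::xml_attr(gp, "id")
    glab <- xml2::xml_attr(gp, "label")
    gp_map <- stats::setNames(ifelse(is.na(glab), gid, glab), gid)
  }
  for (r in rxns) {
    rid <- xml2::xml_attr(r, "id")
    genes <- character(0)
    gpa <- xml2::xml_find_all(
      r, ".//*[local-name() = 'geneProductAssociation']")
    if (length(gpa) > 0) {
      refs <- xml2::xml_find_all(
        gpa[[1]], ".//*[local-name() = 'geneProductRef']")
      ids <- xml2::xml_attr(refs, "geneProduct")
      genes <- ifelse(ids %in% names(gp_map), gp_map[ids], ids)
    } else {
      notes <- xml2::xml_find_all(r, ".//*[local-name() = 'notes']")
      if (length(notes) > 0) {
        txt <- xml2::xml_text(notes[[1]])
        m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n]*", txt))
        if (length(m) == 1) {
          body <- sub("^GENE_ASSOCIATION:", "", m)
          toks <- strsplit(gsub("[()]", " ", body), "\\s+")[[1]]
          genes <- setdiff(toks, c("", "and", "or", "AND", "OR"))
        } else if (grepl("GENE", txt, fixed = TRUE)) {
          warning("reaction '", rid, "': unparseable gene association")
          n_unparsed <- n_unparsed + 1L
        }
      }
    }
    out[[rid]] <- unique(genes)
  }
  attr(out, "n_unparsed") <- n_unparsed
  out
}

#' Pool gene z-scores per reaction
#'
#' Pooled z is the plain sum of the z-scores of all associated genes present
#' in the table (genes absent from the table contribute 0 and are counted in
#' `n_missing_genes`). Reactions mapping to identical gene sets are collapsed
#' to one representative, chosen deterministically as the lexicographically
#' smallest reaction id. Significance requires pooled z strictly greater
#' than 3 (one-sided rule on the summed signed z-scores).
#'
#' @param associations Output of [load_gene_associations()] (or a named list
#'   of gene-id vectors).
#' @param gene_z Named numeric vector of gene z-scores (finite).
#' @param z_cut Significance cutoff (default 3, strict inequality).
#' @param normalize If `TRUE`, divide the pooled sum by `sqrt(k)` (Stouffer
#'   form); default `FALSE`, the plain sum.
#' @return Data frame with `reaction`, `genes` (collapsed, `;`-separated),
#'   `n_genes`, `pooled_z`, `significant`, `n_represented` (how many
#'   reactions share the gene set); attribute `n_missing_genes`.
#' @export
pool_reaction_z <- function(associations, gene_z, z_cut = 3,
                            normalize = FALSE) {
  stopifnot(all(is.finite(gene_z)))
  keep <- vapply(associations, length, integer(1)) > 0
  associations <- associations[keep]
  if (length(associations) == 0)
    return(data.frame(reaction = character(), genes = character(),
                      n_genes = integer(), pooled_z = numeric(),
                      significant = logical(), n_represented = integer()))
  sets <- vapply(associations, function(g)
    paste(sort(unique(g)), collapse = ";"), character(1))
  missing_total <- 0L
  rows <- lapply(split(names(associations), sets), function(rids) {
    rid <- sort(rids)[1]
    genes <- sort(unique(associations[[rid]]))
    present <- genes %in% names(gene_z)
    missing_total <<- missing_total + sum(!present)
    z <- sum(gene_z[genes[present]])
    if (normalize && sum(present) > 0) z <- z / sqrt(sum(present))
    data.frame(reaction = rid, genes = paste(genes, collapse = ";"),
               n_genes = length(genes), pooled_z = z,
               significant = z > z_cut, n_represented = length(rids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$reaction), ]
  rownames(out) <- NULL
  attr(out, "n_missing_genes") <- missing_total
  out
}
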