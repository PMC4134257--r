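#' Parse a minimal OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas and retains term accessions together with `is_a`
#' and `relationship: part_of` edges (child -> parent). Obsolete terms are
#' kept as nodes but contribute no edges. This is deliberately a small
#' subset of OBO: enough to take the transitive closure of a seed term set.
#'
#' @param path path to an OBO flat file.
#' @return list with `terms` (character) and `edges` (data frame with
#'   columns `child`, `parent`, `relation`).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  terms <- character()
  child <- parent <- relation <- character()
  cur <- NA_character_
  in_term <- FALSE
  obsolete <- FALSE
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln))
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA; obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (grepl("^is_obsolete: *true", ln)) {
      obsolete <- TRUE
    } else if (grepl("^is_a:", ln) && !obsolete && !is.na(cur)) {
      child <- c(child, cur)
      parent <- c(parent, trimws(sub("^is_a:", "", ln)))
      relation <- c(relation, "is_a")
    } else if (grepl("^relationship: *part_of", ln) && !obsolete &&
               !is.na(cur)) {
      child <- c(child, cur)
      parent <- c(parent, trimws(sub("^relationship: *part_of", "", ln)))
      relation <- c(relation, "part_of")
    }
  }
  list(terms = unique(terms),
       edges = data.frame(child = child, parent = parent,
                          relation = relation, stringsAsFactors = FALSE))
}

#' Expand a GO term set to its ontology descendants
#'
#' Returns the seeds together with every term reachable from a seed by
#' following the chosen relations downward (i.e. all descendants). Output
#' order is deterministic: seeds in input order, then new descendants
#' sorted lexicographically.
#'
#' @param ontology a parsed ontology from [parse_obo()].
#' @param seeds character vector of seed accessions; all must exist in the
#'   ontology.
#' @param relations subset of `c("is_a", "part_of")`.
#' @return character vector of accessions (unique).
#' @export
expand_term_set <- function(ontology, seeds,
                            relations = c("is_a", "part_of")) {
  stopifnot(all(relations %in% c("is_a", "part_of")))
  unknown <- setdiff(seeds, ontology$terms)
  if (length(unknown))
    stop("seed accession(s) not in ontology: ",
         paste(unknown, collapse = ", "))
  edges <- ontology$edges[ontology$edges$relation %in% relations, ,
                          drop = FALSE]
  children_of <- split(edges$child, edges$parent)
  seen <- unique(seeds)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  c(unique(seeds), sort(setdiff(seen, seeds)))
}

#' Knowledge-based SNP selection (KB-SNP)
#'
#' Keeps each SNP whose annotated gene(s) carry at least one GO term from
#' the target list. SNPs with no gene annotation (intergenic) are never
#' selected. The target list is used verbatim; apply [expand_term_set()]
#' first if an ontology closure is wanted.
#'
#' @param annotation SNP annotation data frame ([read_snp_annotation()]
#'   schema: `snp_id`, `gene_symbols` list column, ...).
#' @param gene_go named list mapping gene symbol -> GO accessions.
#' @param targets character vector of target GO accessions.
#' @return object of class `kb_selection`: list with `selected_snp_ids`
#'   (ordered as in the annotation) and `justification` (data frame
#'   `snp_id`, `gene`, `matched_terms` comma-joined).
#' @export
select_snps_by_go <- function(annotation, gene_go, targets) {
  targets <- unique(targets)
  sel <- character()
  js <- jg <- jt <- character()
  for (i in seq_len(nrow(annotation))) {
    genes <- annotation$gene_symbols[[i]]
    if (!length(genes)) next
    hit <- FALSE
    for (g in genes) {
      m <- intersect(gene_go[[g]], targets)
      if (length(m)) {
        hit <- TRUE
        js <- c(js, annotation$snp_id[i]); jg <- c(jg, g)
        jt <- c(jt, paste(sort(m), collapse = ","))
      }
    }
    if (hit) sel <- c(sel, annotation$snp_id[i])
  }
  if (!length(sel)) message("KB-SNP selection is empty")
  structure(list(selected_snp_ids = sel,
                 justification = data.frame(snp_id = js, gene = jg,
                                            matched_terms = jt,
                                            stringsAsFactors = FALSE)),
            class = "kb_selection")
}

#' @export
print.kb_selection <- function(x, ...) {
  cat(sprintf("kb_selection: %d SNP(s) selected\n",
              length(x$selected_snp_ids)))
  invisible(x)
}

#' Write a KB selection report
#'
#' @param x a `kb_selection`.
#' @param path output TSV path (snp_id, gene, matched_terms).
#' @return `path`, invisibly.
#' @export
write_kb_selection <- function(x, path) {
  utils::write.table(x$justification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
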