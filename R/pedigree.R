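#' Pedigree tables
#'
#' A pedigree is represented as a plain `data.frame` with one row per
#' individual and the columns
#' `id`, `family_id`, `father_id`, `mother_id` (`NA` when the parent is not in
#' the study), `sex` (`"male"`/`"female"`), `affected` (logical),
#' `excluded_parent` (logical; `TRUE` for parents with a diagnosis of the
#' disorder or intellectual disability, who must not seed transmission or
#' pseudocontrol analyses), `cognitive_impairment` (logical, `NA` when
#' unknown), `sequenced` (logical) and `twin_group` (character, `NA` unless
#' the individual belongs to a declared monozygotic twin group).
#'
#' `as_pedigree()` validates and normalises such a table; `read_ped()` builds
#' one from a PED-style file.
#'
#' @param x a data.frame with at least `id`, `family_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`.
#' @return A validated pedigree `data.frame` with all canonical columns.
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("id", "family_id", "father_id", "mother_id", "sex", "affected")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$id))
    stop("duplicated individual ids in pedigree")
  for (col in c("excluded_parent", "sequenced"))
    if (is.null(x[[col]])) x[[col]] <- if (col == "sequenced") TRUE else FALSE
  x$excluded_parent[is.na(x$excluded_parent)] <- FALSE
  x$sequenced[is.na(x$sequenced)] <- TRUE
  if (is.null(x$cognitive_impairment)) x$cognitive_impairment <- NA
  if (is.null(x$twin_group)) x$twin_group <- NA_character_
  x$id <- as.character(x$id)
  x$family_id <- as.character(x$family_id)
  x$father_id <- as.character(x$father_id)
  x$mother_id <- as.character(x$mother_id)
  x$father_id[x$father_id %in% c("0", "")] <- NA_character_
  x$mother_id[x$mother_id %in% c("0", "")] <- NA_character_

  ## parent links must stay within the family and respect sex
  idx <- match(x$father_id, x$id)
  bad <- !is.na(x$father_id) & (is.na(idx) | x$family_id[idx] != x$family_id)
  if (any(bad))
    stop("father of ", paste(x$id[bad], collapse = ","), " not found in the same family")
  if (any(x$sex[idx[!is.na(idx)]] != "male"))
    stop("a referenced father is not male")
  idx <- match(x$mother_id, x$id)
  bad <- !is.na(x$mother_id) & (is.na(idx) | x$family_id[idx] != x$family_id)
  if (any(bad))
    stop("mother of ", paste(x$id[bad], collapse = ","), " not found in the same family")
  if (any(x$sex[idx[!is.na(idx)]] != "female"))
    stop("a referenced mother is not female")
  if (is.null(.pedigree_order(x)))
    stop("parent-child links contain a cycle")
  x
}

#' Read a PED-format pedigree file
#'
#' Reads the standard 6-column PED layout (`FID IID PAT MAT SEX PHENO`,
#' `0` = missing, sex 1 = male / 2 = female, phenotype 2 = affected), tab- or
#' space-delimited, plus optional extension columns named in the header:
#' `excluded_parent`, `twin_group`, `cognitive_impairment`, `sequenced`.
#' A header line is detected by a leading `FID` token (optionally `#FID`).
#'
#' @param path path to the PED file.
#' @return A pedigree `data.frame` (see [as_pedigree()]).
#' @export
read_ped <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^#?FID\\b", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                           comment.char = "", check.names = FALSE)
  if (has_header) names(tab)[1] <- sub("^#", "", names(tab)[1])
  if (!has_header)
    names(tab)[1:6] <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENO")
  ped <- data.frame(
    id = as.character(tab$IID),
    family_id = as.character(tab$FID),
    father_id = as.character(tab$PAT),
    mother_id = as.character(tab$MAT),
    sex = ifelse(tab$SEX == 1, "male", ifelse(tab$SEX == 2, "female", NA)),
    affected = tab$PHENO == 2,
    stringsAsFactors = FALSE
  )
  for (col in c("excluded_parent", "cognitive_impairment", "sequenced"))
    if (col %in% names(tab)) ped[[col]] <- as.logical(tab[[col]])
  if ("twin_group" %in% names(tab)) {
    tg <- as.character(tab$twin_group)
    tg[tg %in% c("0", "", "NA")] <- NA_character_
    ped$twin_group <- tg
  }
  as_pedigree(ped)
}

## topological order of one family (founders first); NULL if cyclic
.pedigree_order <- function(fam) {
  placed <- character(0)
  remaining <- fam$id
  repeat {
    idx <- match(remaining, fam$id)
    ready <- (is.na(fam$father_id[idx]) | fam$father_id[idx] %in% placed) &
             (is.na(fam$mother_id[idx]) | fam$mother_id[idx] %in% placed)
    if (!any(ready)) {
      if (length(remaining) == 0) return(placed)
      return(NULL)
    }
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
    if (length(remaining) == 0) return(placed)
  }
}

#' Kinship matrix of one family
#'
#' Computes the full matrix of kinship coefficients phi for the members of one
#' family by the standard recursion over a founder-first ordering: founders
#' are assumed non-inbred and mutually unrelated, `phi(i,i) = 1/2 (1 + F_i)`
#' with `F_i = phi(father_i, mother_i)`, and
#' `phi(i,j) = 1/2 (phi(father_i, j) + phi(mother_i, j))` for `j` not a
#' descendant of `i` (missing parents contribute 0).
#'
#' @param ped a pedigree `data.frame` (possibly multi-family).
#' @param family family id to compute; may be omitted when `ped` holds a
#'   single family.
#' @return A symmetric numeric matrix with dimnames equal to individual ids.
#' @export
kinship_matrix <- function(ped, family = NULL) {
  ped <- as_pedigree(ped)
  if (is.null(family)) {
    fams <- unique(ped$family_id)
    if (length(fams) != 1)
      stop("ped contains several families; give `family`")
    family <- fams
  }
  fam <- ped[ped$family_id == family, , drop = FALSE]
  if (nrow(fam) == 0) stop("unknown family: ", family)
  ord <- .pedigree_order(fam)
  n <- length(ord)
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  fa <- fam$father_id[match(ord, fam$id)]
  mo <- fam$mother_id[match(ord, fam$id)]
  half <- function(p, j) if (is.na(p)) 0 else phi[p, j]
  for (i in seq_len(n)) {
    ii <- ord[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        jj <- ord[j]
        phi[ii, jj] <- phi[jj, ii] <- 0.5 * (half(fa[i], jj) + half(mo[i], jj))
      }
    }
    f_inbr <- if (is.na(fa[i]) || is.na(mo[i])) 0 else phi[fa[i], mo[i]]
    phi[ii, ii] <- 0.5 * (1 + f_inbr)
  }
  phi
}

#' Kinship coefficient between two individuals
#'
#' Standard recursive kinship phi in `[0, 0.5]`; individuals from different
#' families are unrelated (phi = 0) since founders are assumed mutually
#' unrelated.
#'
#' @param ped pedigree `data.frame`.
#' @param a,b individual ids.
#' @return The kinship coefficient, symmetric in `(a, b)`.
#' @examples
#' trio <- data.frame(id = c("f", "m", "c"), family_id = "F1",
#'                    father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"),
#'                    sex = c("male", "female", "male"),
#'                    affected = c(FALSE, FALSE, TRUE))
#' kinship_coefficient(trio, "f", "c")  # 0.25
#' @export
kinship_coefficient <- function(ped, a, b) {
  ped <- as_pedigree(ped)
  for (id in c(a, b))
    if (!id %in% ped$id) stop("unknown individual id: ", id)
  fam_a <- ped$family_id[match(a, ped$id)]
  fam_b <- ped$family_id[match(b, ped$id)]
  if (fam_a != fam_b) return(0)
  phi <- kinship_matrix(ped, fam_a)
  phi[a, b]
}

#' Build the relatedness graph used to select unrelated samples
#'
#' Nodes are individuals; edges connect pairs with a declared first- or
#' second-degree pedigree relationship (kinship phi >= 0.125 within a family)
#' or pairs without a known familial relationship whose externally estimated
#' kinship coefficient is at or above `threshold`. In X-chromosome mode,
#' father-son pairs are treated as unrelated and contribute no declared edge.
#'
#' @param peds pedigree `data.frame` (all families).
#' @param inferred optional data.frame with columns `id1`, `id2`, `kinship`
#'   holding genotype-based kinship estimates for cryptic relatedness (an
#'   input; genotype-based estimation is not performed here).
#' @param threshold kinship threshold for inferred edges (default 0.1).
#' @param x_mode logical; `TRUE` drops father-son declared edges.
#' @return An [igraph::graph] with vertex attribute `name` and edge attribute
#'   `source` in `{"declared", "inferred_kinship"}`.
#' @export
build_relatedness_graph <- function(peds, inferred = NULL, threshold = 0.1,
                                    x_mode = FALSE) {
  peds <- as_pedigree(peds)
  edges <- character(0)
  src <- character(0)
  for (famid in unique(peds$family_id)) {
    fam <- peds[peds$family_id == famid, , drop = FALSE]
    if (nrow(fam) == 1) next
    phi <- kinship_matrix(peds, famid)
    ids <- rownames(phi)
    for (i in seq_along(ids)[-1]) {
      for (j in seq_len(i - 1)) {
        if (phi[i, j] < 0.125) next
        if (x_mode) {
          a <- fam[match(ids[i], fam$id), ]
          b <- fam[match(ids[j], fam$id), ]
          father_son <- (identical(b$father_id, a$id) && b$sex == "male") ||
                        (identical(a$father_id, b$id) && a$sex == "male")
          if (isTRUE(father_son)) next
        }
        edges <- c(edges, ids[i], ids[j])
        src <- c(src, "declared")
      }
    }
  }
  if (!is.null(inferred) && nrow(inferred) > 0) {
    if (any(inferred$kinship < 0 | inferred$kinship > 0.5))
      stop("inferred kinship estimates must lie in [0, 0.5]")
    keep <- inferred$kinship >= threshold
    if (any(keep)) {
      edges <- c(edges, as.vector(rbind(as.character(inferred$id1[keep]),
                                        as.character(inferred$id2[keep]))))
      src <- c(src, rep("inferred_kinship", sum(keep)))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(peds), name = peds$id)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, match(edges, peds$id))
    igraph::E(g)$source <- src
  }
  g
}

#' Select one individual per connected component of the relatedness graph
#'
#' Deterministic rule: within each connected component, affected individuals
#' have priority over unaffected ones, ties broken by the lexicographically
#' smallest id. The result is a maximal independent choice of one sample per
#' component.
#'
#' @param g relatedness graph from [build_relatedness_graph()].
#' @param peds pedigree `data.frame` supplying affection status (optional; if
#'   omitted the smallest id wins).
#' @return Character vector of selected ids, one per component.
#' @export
select_unrelated <- function(g, peds = NULL) {
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  affected <- if (is.null(peds)) rep(FALSE, length(ids)) else
    as.logical(peds$affected[match(ids, peds$id)])
  affected[is.na(affected)] <- FALSE
  picked <- vapply(seq_len(comp$no), function(k) {
    members <- ids[comp$membership == k]
    aff <- affected[comp$membership == k]
    pool <- if (any(aff)) members[aff] else members
    sort(pool)[1]
  }, character(1))
  sort(picked)
}

## closest sequenced, unaffected, non-excluded ancestor on each parental
## lineage; search stops at the first qualifying hit per lineage
.recent_unaffected_ancestors <- function(fam, id) {
  res <- character(0)
  climb <- function(pid) {
    if (is.na(pid) || !(pid %in% fam$id)) return(invisible())
    r <- fam[match(pid, fam$id), ]
    if (isTRUE(r$sequenced) && !isTRUE(r$affected) && !isTRUE(r$excluded_parent)) {
      res <<- c(res, pid)
      return(invisible())
    }
    climb(r$father_id)
    climb(r$mother_id)
  }
  me <- fam[match(id, fam$id), ]
  climb(me$father_id)
  climb(me$mother_id)
  unique(res)
}

#' Contributing sample size of a case
#'
#' A case contributes `1 - sum(phi(case, ancestor))` to the case-control
#' analysis, summed over its most recent sequenced, unaffected,
#' non-excluded ancestors (closest qualifying ancestor per parental lineage),
#' floored at 0. A trio case with both unaffected parents sequenced therefore
#' contributes 0.5, a duo case 0.75, and a case with no sequenced unaffected
#' ancestors 1. Cases with weight 0 are excluded from case-control.
#'
#' @param ped pedigree `data.frame`.
#' @param case_id id of an affected, sequenced individual.
#' @return A list with `individual_id`, `weight` and `ancestors` (ids used).
#' @export
contributing_sample_size <- function(ped, case_id) {
  ped <- as_pedigree(ped)
  if (!case_id %in% ped$id) stop("unknown individual id: ", case_id)
  famid <- ped$family_id[match(case_id, ped$id)]
  fam <- ped[ped$family_id == famid, , drop = FALSE]
  anc <- .recent_unaffected_ancestors(fam, case_id)
  w <- 1
  if (length(anc) > 0) {
    phi <- kinship_matrix(ped, famid)
    w <- max(0, 1 - sum(phi[case_id, anc]))
  }
  list(individual_id = case_id, weight = w, ancestors = anc)
}

## parents of at least one affected sequenced offspring, themselves sequenced,
## unaffected and without the diagnosis-exclusion flag
.eligible_parents <- function(peds) {
  kids <- peds[peds$affected & peds$sequenced, , drop = FALSE]
  parents <- unique(stats::na.omit(c(kids$father_id, kids$mother_id)))
  keep <- parents %in% peds$id[peds$sequenced & !peds$affected & !peds$excluded_parent]
  parents[keep]
}

.count_by_gene <- function(gene_ids) {
  if (length(gene_ids) == 0)
    return(data.frame(gene_id = character(0), carriers = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(gene_ids)
  data.frame(gene_id = names(tab), carriers = as.integer(tab),
             stringsAsFactors = FALSE)
}

.filter_variants <- function(variants, max_af = 1e-5,
                             require_high_confidence = TRUE,
                             classes = "lof") {
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(max_af) && "af" %in% names(variants))
    keep <- keep & variants$af <= max_af
  if (require_high_confidence && "high_confidence" %in% names(variants))
    keep <- keep & variants$high_confidence
  if (!is.null(classes) && "variant_class" %in% names(variants))
    keep <- keep & variants$variant_class %in% classes
  variants[keep, , drop = FALSE]
}

#' Construct pseudocontrol allele counts from untransmitted parental alleles
#'
#' Pseudocontrols are built from sequenced, unaffected, non-excluded parents
#' of affected offspring, using alleles that were not transmitted to any
#' affected offspring. Each eligible parent contributes a sample size of 0.5,
#' whether or not they carry a qualifying allele. For female-X analyses
#' (`x_mode = TRUE`) only unaffected mothers are used and an allele counts as
#' untransmitted when no affected son carries it.
#'
#' @param peds pedigree `data.frame`.
#' @param variants variant observation `data.frame` with columns
#'   `individual_id`, `gene_id`, `allele_id`, `variant_class`, `af`,
#'   `high_confidence` (and optionally `chrom_class`).
#' @param max_af,require_high_confidence,classes allele filters (defaults:
#'   allele frequency below 1e-5, high-confidence LoF).
#' @param x_mode female-X variant of the construction.
#' @return List with `counts` (data.frame `gene_id`, `carriers`), `n_eff`
#'   (0.5 x number of eligible parents) and `parents` (ids).
#' @export
construct_pseudocontrols <- function(peds, variants, max_af = 1e-5,
                                     require_high_confidence = TRUE,
                                     classes = "lof", x_mode = FALSE) {
  peds <- as_pedigree(peds)
  parents <- .eligible_parents(peds)
  if (x_mode)
    parents <- parents[peds$sex[match(parents, peds$id)] == "female"]
  v <- .filter_variants(variants, max_af, require_high_confidence, classes)
  pv <- v[v$individual_id %in% parents, , drop = FALSE]
  child_keys <- paste(v$individual_id, v$allele_id)
  untransmitted <- logical(nrow(pv))
  for (i in seq_len(nrow(pv))) {
    p <- pv$individual_id[i]
    kids <- peds$id[peds$affected & peds$sequenced &
                    (peds$father_id %in% p | peds$mother_id %in% p)]
    if (x_mode)
      kids <- kids[peds$sex[match(kids, peds$id)] == "male"]
    untransmitted[i] <- !any(paste(kids, pv$allele_id[i]) %in% child_keys)
  }
  counts <- .count_by_gene(pv$gene_id[untransmitted])
  list(counts = counts, n_eff = 0.5 * length(parents), parents = parents)
}

#' Construct pseudocase allele counts
#'
#' For every affected, sequenced case with positive contributing sample size,
#' qualifying alleles are retained only when they were not observed in any of
#' the case's sampled unaffected ancestors (the set used by the TDT) and are
#' not in the supplied de novo allele set. The effective sample size is the
#' sum of the contributing weights.
#'
#' @inheritParams construct_pseudocontrols
#' @param dnv_alleles character vector of `allele_id`s already counted in the
#'   de novo analysis; these are removed from pseudocases.
#' @return List with `counts` (data.frame `gene_id`, `carriers`), `n_eff`,
#'   `weights` (named per-case contributing sample sizes) and `rows` (the
#'   retained allele observations).
#' @export
construct_pseudocases <- function(peds, variants, dnv_alleles = character(0),
                                  max_af = 1e-5, require_high_confidence = TRUE,
                                  classes = "lof") {
  peds <- as_pedigree(peds)
  v <- .filter_variants(variants, max_af, require_high_confidence, classes)
  cases <- peds$id[peds$affected & peds$sequenced]
  ## one twin per declared monozygotic twin group
  tw <- peds$twin_group[match(cases, peds$id)]
  cases <- cases[!(duplicated(tw) & !is.na(tw))]

  key <- paste(v$individual_id, v$allele_id)
  rows_by_ind <- split(seq_len(nrow(v)), v$individual_id)
  fam_split <- split(peds, peds$family_id)
  case_fam <- peds$family_id[match(cases, peds$id)]

  weights <- numeric(0)
  keep_rows <- integer(0)
  for (famid in unique(case_fam)) {
    fam <- fam_split[[famid]]
    fam_cases <- cases[case_fam == famid]
    phi <- NULL
    for (cs in fam_cases) {
      anc <- .recent_unaffected_ancestors(fam, cs)
      w <- 1
      if (length(anc) > 0) {
        if (is.null(phi)) phi <- kinship_matrix(fam, famid)
        w <- max(0, 1 - sum(phi[cs, anc]))
      }
      if (w <= 0) next
      weights[cs] <- w
      rows <- rows_by_ind[[cs]]
      if (is.null(rows)) next
      seen_in_anc <- if (length(anc) > 0) vapply(rows, function(r)
        any(paste(anc, v$allele_id[r]) %in% key), logical(1))
      else rep(FALSE, length(rows))
      is_dnv <- v$allele_id[rows] %in% dnv_alleles
      keep_rows <- c(keep_rows, rows[!seen_in_anc & !is_dnv])
    }
  }
  counts <- .count_by_gene(v$gene_id[keep_rows])
  list(counts = counts, n_eff = sum(weights), weights = weights,
       rows = v[keep_rows, , drop = FALSE])
}

#' Count trio and duo families among affected offspring
#'
#' A trio has both parents sequenced and non-excluded; a duo exactly one.
#' Counting is per affected, sequenced offspring (monozygotic twins counted
#' once).
#'
#' @param peds pedigree `data.frame`.
#' @return List with `n_trios` and `n_duos`.
#' @export
count_family_types <- function(peds) {
  peds <- as_pedigree(peds)
  kids <- peds[peds$affected & peds$sequenced, , drop = FALSE]
  drop <- duplicated(kids$twin_group) & !is.na(kids$twin_group)
  kids <- kids[!drop, , drop = FALSE]
  ok_parent <- function(pid) {
    idx <- match(pid, peds$id)
    !is.na(idx) & peds$sequenced[idx] & !peds$excluded_parent[idx] & !peds$affected[idx]
  }
  n_par <- ok_parent(kids$father_id) + ok_parent(kids$mother_id)
  list(n_trios = sum(n_par == 2), n_duos = sum(n_par == 1))
}
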