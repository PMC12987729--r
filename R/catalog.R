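# Signature-gene selection from pangenomes and KEGG module association.

#' Select signature genes for a species from its pangenome
#'
#' Signature genes are core genes (prevalence across the species' MAGs of
#' at least 60%) with length between 200 bp and 20 kb that carry species
#' uniqueness evidence (no shared 100 bp segment at more than 97% identity
#' with any other catalog gene, supplied here as a precomputed boolean).
#' Up to `cap` genes are selected with the deterministic priority: higher
#' prevalence, then longer gene, then lexicographic gene id.
#'
#' @param pangenome data.frame with columns `gene_id`, `length` (bp),
#'   `prevalence` (fraction of MAGs containing the gene) and `unique`
#'   (logical uniqueness evidence).
#' @param cap maximum number of signature genes (default 250).
#' @return data.frame of selected genes in priority order; attribute
#'   `fallback_needed` is `TRUE` when fewer than 20 genes were eligible
#'   (the masking fallback used in that situation is out of scope here).
#' @export
select_signature_genes <- function(pangenome, cap = 250) {
  if (nrow(pangenome) == 0) stopf("pangenome is empty")
  check_number(cap, "cap", lower = 1)
  eligible <- pangenome[pangenome$prevalence >= 0.60 &
                          pangenome$length >= 200 &
                          pangenome$length <= 20000 &
                          pangenome$unique, , drop = FALSE]
  fallback <- nrow(eligible) < 20
  ord <- order(-eligible$prevalence, -eligible$length, eligible$gene_id)
  out <- eligible[ord[seq_len(min(cap, nrow(eligible)))], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fallback_needed") <- fallback
  out
}

#' Define a KEGG module
#'
#' A module is one or more alternative reaction paths; each path is an
#' ordered list of steps and each step is a set of one or more KOs.
#'
#' @param module_id character module id.
#' @param paths list of paths; each path is a list of character vectors
#'   (the KO sets of its steps).
#' @return object of class `kegg_module`.
#' @export
kegg_module <- function(module_id, paths) {
  if (length(paths) < 1) stopf("module %s must have at least one path",
                               module_id)
  for (p in paths) {
    if (length(p) < 1 || any(lengths(p) == 0)) {
      stopf("module %s has an empty path or step", module_id)
    }
  }
  structure(list(module_id = module_id, paths = paths),
            class = "kegg_module")
}

#' Species-module association by completeness criteria
#'
#' A species is associated with a module when, for at least one of the
#' module's alternative paths, the species' KO set covers at least 2/3 of
#' the distinct KOs of that path — and, for paths with three or fewer
#' steps, every step has at least one KO present.
#'
#' @param species_kos character vector of KOs annotated to the species.
#' @param module a [kegg_module()].
#' @return list with `associated` (logical), `completeness` (the best
#'   qualifying — or best overall — path's KO coverage fraction),
#'   `path` (index of that path) and `small_module_rule` (whether the
#'   all-steps rule was applied to the deciding path).
#' @export
species_module_association <- function(species_kos, module) {
  best <- list(associated = FALSE, completeness = 0, path = NA_integer_,
               small_module_rule = FALSE)
  for (i in seq_along(module$paths)) {
    path <- module$paths[[i]]
    kos <- unique(unlist(path))
    comp <- mean(kos %in% species_kos)
    small <- length(path) <= 3
    steps_ok <- all(vapply(path, function(st) any(st %in% species_kos),
                           logical(1)))
    ok <- comp >= 2 / 3 && (!small || steps_ok)
    if (ok && (!best$associated || comp > best$completeness)) {
      best <- list(associated = TRUE, completeness = comp, path = i,
                   small_module_rule = small)
    } else if (!best$associated && comp > best$completeness) {
      best$completeness <- comp
      best$path <- i
      best$small_module_rule <- small
    }
  }
  best
}

#' Species-module association matrix
#'
#' Applies [species_module_association()] over all species and modules.
#'
#' @param species_ko_sets named list: species id -> character vector of
#'   KOs carried by that species.
#' @param modules list of [kegg_module()] objects.
#' @return logical species x modules matrix with a numeric `completeness`
#'   attribute matrix of the deciding path coverage.
#' @export
module_association_matrix <- function(species_ko_sets, modules) {
  ids <- vapply(modules, function(m) m$module_id, character(1))
  out <- matrix(FALSE, length(species_ko_sets), length(modules),
                dimnames = list(names(species_ko_sets), ids))
  comp <- out * 0
  for (s in seq_along(species_ko_sets)) {
    for (m in seq_along(modules)) {
      r <- species_module_association(species_ko_sets[[s]], modules[[m]])
      out[s, m] <- r$associated
      comp[s, m] <- r$completeness
    }
  }
  attr(out, "completeness") <- comp
  out
}

#' KEGG module abundance profile
#'
#' The functional-potential value of a module in a sample is the sum of
#' the relative abundances of the species associated with that module.
#'
#' @param profile samples x species relative abundance matrix (percent).
#' @param assoc logical species x modules association matrix (as from
#'   [module_association_matrix()]).
#' @return samples x modules matrix with values in `[0, 100]`.
#' @export
module_abundance_profile <- function(profile, assoc) {
  profile <- as.matrix(profile)
  sp <- colnames(profile)
  if (!setequal(sp, rownames(assoc))) {
    stopf("species in profile and association matrix differ")
  }
  profile %*% (assoc[sp, , drop = FALSE] * 1)
}

#' Read / write KEGG module definitions as TSV
#'
#' The TSV has columns `module`, `path`, `step`, `kos` (comma-separated KO
#' list for the step), one row per step.
#'
#' @param path file path.
#' @param modules list of [kegg_module()] objects (for writing).
#' @return `read_module_defs` returns a list of [kegg_module()] objects.
#' @export
read_module_defs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$module), function(md) {
    paths <- lapply(split(md, md$path), function(pd) {
      pd <- pd[order(pd$step), , drop = FALSE]
      lapply(strsplit(pd$kos, ","), trimws)
    })
    kegg_module(md$module[1], unname(paths))
  })
}

#' @rdname read_module_defs
#' @export
write_module_defs <- function(modules, path) {
  rows <- do.call(rbind, lapply(modules, function(m) {
    do.call(rbind, lapply(seq_along(m$paths), function(i) {
      data.frame(module = m$module_id, path = i,
                 step = seq_along(m$paths[[i]]),
                 kos = vapply(m$paths[[i]], paste, character(1),
                              collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
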