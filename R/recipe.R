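#' A named set of transcript clusters with provenance
#'
#' @param name Human-readable list name.
#' @param cluster_ids Character vector of transcript cluster ids.
#' @param gene_symbols Symbols parallel to `cluster_ids`.
#' @param recipe The recipe (list of steps) that produced the list.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(name, cluster_ids, gene_symbols, recipe) {
  stopifnot(length(cluster_ids) == length(gene_symbols))
  structure(list(name = name,
                 cluster_ids = as.character(cluster_ids),
                 gene_symbols = as.character(gene_symbols),
                 recipe = recipe),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d transcript clusters, %d genes (%d steps)\n",
              x$name, length(x$cluster_ids), gene_level_count(x),
              length(x$recipe$steps)))
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$cluster_ids)

#' Number of distinct gene symbols in a list
#'
#' Counts at the gene level ("each gene was counted only once"); empty
#' symbols are ignored.
#' @param x A [gene_list()].
#' @return Integer count of distinct non-empty symbols.
#' @export
gene_level_count <- function(x) {
  length(unique(x$gene_symbols[nzchar(x$gene_symbols)]))
}

#' Recipe step constructors
#'
#' A recipe is an ordered list of steps evaluated by [evaluate_recipe()]:
#' `step_compare()` keeps clusters whose call in a pairwise comparison equals
#' `wanted` (composed by intersection); `step_exclude()` removes clusters
#' whose call equals `wanted` (the "if the gene was also more highly
#' expressed ... it was removed" constructions); `step_subtract()` removes
#' the members of a previously computed [gene_list()] and is ignored during
#' permutation re-runs.
#'
#' @param a,b Group descriptors from [grp()].
#' @param wanted A call in higher/lower/identical.
#' @param list A [gene_list()] (or character vector of cluster ids) to
#'   subtract.
#' @param note Free-text provenance for subtraction steps.
#' @name recipe_steps
NULL

#' @rdname recipe_steps
#' @export
step_compare <- function(a, b, wanted) {
  stopifnot(wanted %in% c("higher", "lower", "identical"))
  list(type = "compare", a = a, b = b, wanted = wanted)
}

#' @rdname recipe_steps
#' @export
step_exclude <- function(a, b, wanted) {
  stopifnot(wanted %in% c("higher", "lower", "identical"))
  list(type = "exclude", a = a, b = b, wanted = wanted)
}

#' @rdname recipe_steps
#' @export
step_subtract <- function(list, note = "removal") {
  ids <- if (inherits(list, "gene_list")) list$cluster_ids else as.character(list)
  list(type = "subtract", ids = ids, note = note,
       skip_in_permutation = TRUE)
}

#' Build a recipe from steps
#'
#' @param name List name the evaluated recipe will carry.
#' @param ... Steps from [step_compare()], [step_exclude()],
#'   [step_subtract()].
#' @return An object of class `recipe`.
#' @export
recipe <- function(name, ...) {
  steps <- list(...)
  if (length(steps) == 1 && is.null(steps[[1]]$type)) steps <- steps[[1]]
  if (!any(vapply(steps, function(s) s$type %in% c("compare", "exclude"),
                  TRUE)))
    stop("a recipe needs at least one comparison step")
  structure(list(name = name, steps = steps), class = "recipe")
}

# Samples participating in a recipe's comparison steps (sample-sheet rows).
participating_samples <- function(recipe, samples) {
  idx <- integer(0)
  for (s in recipe$steps) {
    if (s$type %in% c("compare", "exclude"))
      idx <- c(idx, resolve_group(samples, s$a), resolve_group(samples, s$b))
  }
  sort(unique(idx))
}

#' Evaluate a recipe against a study
#'
#' Comparison steps are composed by set intersection (order-independent);
#' exclusion steps and subtraction steps remove members and are applied after
#' all intersections. Each distinct pairwise comparison is computed once and
#' cached within the evaluation.
#'
#' @param study A filtered [expression_study()].
#' @param rec A [recipe()].
#' @param cfg A [threshold_config()].
#' @param samples Optional replacement sample sheet (permutation machinery).
#' @param skip_subtract Ignore subtraction steps (the permutation null).
#' @return A [gene_list()].
#' @export
evaluate_recipe <- function(study, rec, cfg = threshold_config(),
                            samples = NULL, skip_subtract = FALSE) {
  if (is.null(samples)) samples <- study$samples
  cache <- new.env(parent = emptyenv())
  get_calls <- function(a, b) {
    key <- paste(grp_label(a), "|", grp_label(b))
    if (!is.null(cache[[key]])) return(cache[[key]])
    calls <- compare_groups(study, a, b, cfg, samples = samples)
    cache[[key]] <- calls
    calls
  }
  keep <- NULL
  drop <- character(0)
  for (s in rec$steps) {
    if (s$type == "compare") {
      calls <- get_calls(s$a, s$b)
      hit <- calls$cluster_id[calls$call == s$wanted]
      keep <- if (is.null(keep)) hit else intersect(keep, hit)
    } else if (s$type == "exclude") {
      calls <- get_calls(s$a, s$b)
      drop <- c(drop, calls$cluster_id[calls$call == s$wanted])
    } else if (s$type == "subtract") {
      if (!skip_subtract) drop <- c(drop, s$ids)
    } else stop("unknown step type: ", s$type)
  }
  ids <- setdiff(keep, drop)
  gene_list(name = rec$name, cluster_ids = ids,
            gene_symbols = cluster_symbols(study, ids),
            recipe = list(steps = rec$steps))
}

#' Set difference of two gene lists
#'
#' Used for the Leydig-gene and interstitial/stromal removals; the recipe of
#' the result records the removal as a subtraction step, which permutation
#' re-runs ignore.
#'
#' @param target,removal [gene_list()] objects.
#' @param note Provenance note recorded in the recipe.
#' @return The pruned [gene_list()].
#' @export
subtract_list <- function(target, removal, note = NULL) {
  if (is.null(note)) note <- sprintf("removed members of '%s'", removal$name)
  keep <- !target$cluster_ids %in% removal$cluster_ids
  gene_list(name = target$name,
            cluster_ids = target$cluster_ids[keep],
            gene_symbols = target$gene_symbols[keep],
            recipe = list(steps = c(target$recipe$steps,
                                    list(step_subtract(removal, note)))))
}

#' Write a gene list as a two-column delimited table
#'
#' Mirrors the cluster-id / gene-symbol layout of the published list tables
#' (all transcript clusters shown, duplicates not removed).
#' @param x A [gene_list()].
#' @param file Output path.
#' @export
write_gene_list <- function(x, file) {
  utils::write.table(data.frame(cluster_id = x$cluster_ids,
                                gene_symbol = x$gene_symbols),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
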