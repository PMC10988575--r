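# Evaluation split protocols with verifiable disjointness: scaffold splits,
# unseen-molecule k-fold CV, and leave-component-out reaction splits.

new_split_plan <- function(kind, train_ids, test_ids, held_out = NULL) {
  if (length(intersect(train_ids, test_ids)))
    stop("split plan is not disjoint")
  structure(list(kind = kind, train_ids = train_ids, test_ids = test_ids,
                 held_out = held_out),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %s: %d train / %d test%s>\n", x$kind,
              length(x$train_ids), length(x$test_ids),
              if (!is.null(x$held_out))
                paste0(", held out ", x$held_out$role, "=", x$held_out$component)
              else ""))
  invisible(x)
}

#' Serialize a split plan (or list of plans) to JSON
#' @param plan a `split_plan` or list of them.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
split_plan_json <- function(plan, path = NULL) {
  unwrap <- function(p) list(kind = p$kind, train_ids = p$train_ids,
                             test_ids = p$test_ids, held_out = p$held_out)
  payload <- if (inherits(plan, "split_plan")) unwrap(plan) else lapply(plan, unwrap)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

dataset_ids <- function(dataset) {
  nms <- vapply(seq_along(dataset), function(i) {
    g <- as_graph(dataset[[i]])
    if (!is.null(g$name)) g$name else sprintf("record_%04d", i)
  }, character(1))
  if (anyDuplicated(nms)) nms <- sprintf("%s#%d", nms, seq_along(nms))
  nms
}

#' Scaffold split
#'
#' Groups molecules by Bemis-Murcko scaffold and assigns whole scaffold
#' groups greedily (largest group first, ties shuffled by `seed`): a group
#' goes to the training side while it still fits the training budget of
#' `(1 - test_fraction) * n`, otherwise to the test side. No scaffold ever
#' straddles the split, so the realized test fraction is within one scaffold
#' group of the request.
#'
#' @param dataset list of [molecular_graph]s or records with `$graph`.
#' @param test_fraction target test fraction in (0, 1).
#' @param seed tie-break seed.
#' @return A `split_plan` with an extra `scaffolds` attribute mapping ids to
#'   scaffold keys.
#' @export
scaffold_split <- function(dataset, test_fraction = 0.2, seed = 1L) {
  if (!length(dataset)) stop("empty dataset")
  stopifnot(test_fraction > 0, test_fraction < 1)
  ids <- dataset_ids(dataset)
  scaf <- vapply(dataset, function(x) murcko_scaffold(as_graph(x)), character(1))
  groups <- split(ids, scaf)
  if (length(groups) < 2L)
    stop("scaffold split impossible: dataset has a single scaffold")
  set.seed(seed)
  ord <- order(-lengths(groups), sample.int(length(groups)))
  groups <- groups[ord]
  n <- length(ids)
  train_budget <- n - round(test_fraction * n)
  train <- character(); test <- character()
  for (g in groups) {
    if (length(train) + length(g) <= train_budget) train <- c(train, g)
    else test <- c(test, g)
  }
  if (!length(test)) {  # budget swallowed everything; hold out smallest group
    last <- groups[[length(groups)]]
    train <- setdiff(train, last); test <- last
  }
  plan <- new_split_plan("scaffold", train, test)
  attr(plan, "scaffolds") <- stats::setNames(scaf, ids)
  plan
}

#' Unseen-molecule k-fold cross-validation split
#'
#' Partitions the dataset into `k` folds such that each molecule is tested
#' exactly once and duplicate structures (identical canonical form, chirality
#' included) are always co-assigned — so every test molecule is genuinely
#' unseen during that fold's training.
#'
#' @param dataset list of [molecular_graph]s or records with `$graph`.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return A list of `k` `split_plan`s.
#' @export
kfold_unseen <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, length(dataset) >= k)
  ids <- dataset_ids(dataset)
  sigs <- vapply(dataset, function(x) graph_signature(as_graph(x)), character(1))
  groups <- split(ids, sigs)
  if (length(groups) < k)
    stop("fewer unique structures (", length(groups), ") than folds (", k, ")")
  set.seed(seed)
  groups <- groups[sample.int(length(groups))]
  # balance fold sizes: biggest groups first, each to the currently smallest fold
  groups <- groups[order(-lengths(groups))]
  fold_of <- integer(length(groups))
  sizes <- numeric(k)
  for (i in seq_along(groups)) {
    f <- which.min(sizes)
    fold_of[i] <- f
    sizes[f] <- sizes[f] + length(groups[[i]])
  }
  lapply(seq_len(k), function(f) {
    test <- unlist(groups[fold_of == f], use.names = FALSE)
    new_split_plan("kfold_unseen", setdiff(ids, test), test)
  })
}

#' Leave-component-out reaction splits
#'
#' For each named component (e.g. a ligand), all reactions using it in the
#' given role form the test set and the remainder the training set — the
#' evaluation protocol for unseen halides/bases/ligands/additives. By
#' construction every test reaction contains the held-out component and no
#' training reaction does.
#'
#' @param reactions data.frame with one column per role plus outcome columns.
#' @param role role column to hold out on.
#' @param components components to hold out; default every unique value of
#'   the role column (one plan each).
#' @return A list of `split_plan`s (ids are row indices as character).
#' @export
leave_component_out_split <- function(reactions, role, components = NULL) {
  if (!role %in% names(reactions))
    stop("role column not found: ", role)
  vals <- as.character(reactions[[role]])
  if (is.null(components)) components <- unique(vals)
  ids <- as.character(seq_len(nrow(reactions)))
  lapply(components, function(comp) {
    test <- ids[vals == comp]
    if (!length(test))
      stop("component not present in role '", role, "': ", comp)
    train <- setdiff(ids, test)
    if (!length(train))
      stop("component '", comp, "' is used in every reaction: empty train set")
    new_split_plan("leave_component_out", train, test,
                   held_out = list(role = role, component = comp))
  })
}

#' Most common components of a reaction role
#'
#' Convenience for the "most common reactant used as the test split"
#' protocol: returns the top-`n` most frequent components so they can be
#' passed to [leave_component_out_split].
#'
#' @param reactions reaction data.frame.
#' @param role role column name.
#' @param n how many top components.
#' @return Character vector of components, most frequent first.
#' @export
most_common_component <- function(reactions, role, n = 1L) {
  tab <- sort(table(as.character(reactions[[role]])), decreasing = TRUE)
  names(tab)[seq_len(min(n, length(tab)))]
}

#' Audit a split plan for leakage
#'
#' Verifies the defining properties of a plan against its dataset: train/test
#' disjointness, coverage of all ids, scaffold disjointness for scaffold
#' plans, duplicate co-assignment for k-fold plans, and held-out component
#' containment/exclusion for leave-component-out plans. Errors on the first
#' violation; returns TRUE invisibly when clean.
#'
#' @param plan a `split_plan`.
#' @param dataset the dataset (molecule list, or reaction data.frame for
#'   leave-component-out plans).
#' @return TRUE (invisibly) or an error describing the leak.
#' @export
audit_split <- function(plan, dataset) {
  if (length(intersect(plan$train_ids, plan$test_ids)))
    stop("audit: train and test overlap")
  if (plan$kind == "leave_component_out") {
    ids <- as.character(seq_len(nrow(dataset)))
    if (!setequal(c(plan$train_ids, plan$test_ids), ids))
      stop("audit: plan does not cover the reaction table")
    vals <- as.character(dataset[[plan$held_out$role]])
    comp <- plan$held_out$component
    if (!all(vals[as.integer(plan$test_ids)] == comp))
      stop("audit: test reaction without the held-out component")
    if (any(vals[as.integer(plan$train_ids)] == comp))
      stop("audit: held-out component leaked into training")
    return(invisible(TRUE))
  }
  ids <- dataset_ids(dataset)
  if (!setequal(c(plan$train_ids, plan$test_ids), ids))
    stop("audit: plan does not cover the dataset")
  if (plan$kind == "scaffold") {
    scaf <- vapply(dataset, function(x) murcko_scaffold(as_graph(x)),
                   character(1))
    names(scaf) <- ids
    if (length(intersect(unique(scaf[plan$train_ids]),
                         unique(scaf[plan$test_ids]))))
      stop("audit: a scaffold straddles the split")
  }
  if (plan$kind == "kfold_unseen") {
    sigs <- vapply(dataset, function(x) graph_signature(as_graph(x)),
                   character(1))
    names(sigs) <- ids
    if (length(intersect(unique(sigs[plan$train_ids]),
                         unique(sigs[plan$test_ids]))))
      stop("audit: a duplicate structure straddles the split")
  }
  invisible(TRUE)
}
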