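# CART-style classification tree, written in-package because no recursive
# partitioning library is available in the target environment. Binary
# splits, Gini impurity, minimum split size, and pruning by minimum
# relative impurity decrease (cp, as the usual complexity parameter).

gini_impurity <- function(y) {
  p <- tabulate(y, nbins = nlevels(y)) / length(y)
  1 - sum(p^2)
}

best_split_numeric <- function(x, y, min_bucket) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  ux <- unique(xs)
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-length(ux)] + ux[-1L]) / 2
  best <- NULL
  for (cut in cuts) {
    left <- xs < cut
    nl <- sum(left)
    if (nl < min_bucket || n - nl < min_bucket) next
    imp <- nl * gini_impurity(ys[left]) + (n - nl) * gini_impurity(ys[!left])
    if (is.null(best) || imp < best$imp) {
      best <- list(imp = imp, cut = cut)
    }
  }
  best
}

best_split_factor <- function(x, y, min_bucket) {
  x <- droplevels(factor(x))
  lv <- levels(x)
  if (length(lv) < 2L || length(lv) > 8L) {
    if (length(lv) > 8L) stop("factor predictor with > 8 levels", call. = FALSE)
    if (length(lv) < 2L) return(NULL)
  }
  n <- length(x)
  best <- NULL
  # exhaustive subsets holding the first level on the left (complement symmetry)
  others <- lv[-1L]
  for (mask in seq.int(0L, 2L^length(others) - 1L)) {
    subset <- c(lv[1L], others[bitwAnd(mask, 2L^(seq_along(others) - 1L)) > 0])
    left <- x %in% subset
    nl <- sum(left)
    if (nl < min_bucket || n - nl < min_bucket) next
    imp <- nl * gini_impurity(y[left]) + (n - nl) * gini_impurity(y[!left])
    if (is.null(best) || imp < best$imp) {
      best <- list(imp = imp, levels = subset)
    }
  }
  best
}

grow_node <- function(data, response, predictors, id, n_total, root_imp,
                      min_split, min_bucket, cp, depth, max_depth) {
  y <- data[[response]]
  n <- nrow(data)
  counts <- tabulate(y, nbins = nlevels(y))
  props <- counts / n
  node <- list(
    id = id, n = n, coverage_pct = 100 * n / n_total,
    props = stats::setNames(props, levels(y)),
    label = levels(y)[which.max(counts)],
    split_var = NA_character_, split_desc = NA_character_,
    split_cut = NA_real_, split_levels = NULL,
    children = NULL
  )
  if (n < min_split || depth >= max_depth || gini_impurity(y) == 0) {
    return(list(node))
  }
  node_imp <- n * gini_impurity(y)
  best <- NULL
  for (v in predictors) {
    x <- data[[v]]
    ok <- !is.na(x)
    if (sum(ok) < min_split) next
    s <- if (is.numeric(x)) best_split_numeric(x[ok], y[ok], min_bucket)
         else best_split_factor(x[ok], y[ok], min_bucket)
    if (is.null(s)) next
    # charge unseparated NA rows at the node impurity rate so predictors
    # with missing values are not favoured
    s$imp <- s$imp + sum(!ok) * gini_impurity(y)
    if (is.null(best) || s$imp < best$imp) { best <- s; best$var <- v }
  }
  if (is.null(best)) return(list(node))
  gain <- node_imp - best$imp
  if (gain < cp * root_imp) return(list(node))   # complexity pruning

  x <- data[[best$var]]
  if (!is.null(best$cut)) {
    left <- x < best$cut
    node$split_cut <- best$cut
    node$split_desc <- sprintf("%s < %g", best$var, best$cut)
  } else {
    left <- x %in% best$levels
    node$split_levels <- best$levels
    node$split_desc <- sprintf("%s in {%s}", best$var,
                               paste(best$levels, collapse = ","))
  }
  # no surrogate splits: missing values follow the majority branch
  if (anyNA(left)) left[is.na(left)] <- sum(left, na.rm = TRUE) >= n / 2
  node$split_var <- best$var
  node$children <- c(2L * id, 2L * id + 1L)
  c(list(node),
    grow_node(data[left, , drop = FALSE], response, predictors, 2L * id,
              n_total, root_imp, min_split, min_bucket, cp, depth + 1L,
              max_depth),
    grow_node(data[!left, , drop = FALSE], response, predictors, 2L * id + 1L,
              n_total, root_imp, min_split, min_bucket, cp, depth + 1L,
              max_depth))
}

#' Classification tree for survival or injury outcomes
#'
#' Binary CART with Gini impurity. Left branches answer the split
#' question affirmatively; nodes are numbered root = 1, children of node
#' i = 2i and 2i + 1 (skipped numbers correspond to non-existing nodes).
#' For a binary dead/alive response, nodes are labeled by the 50 percent
#' rule. When no split passes the complexity control the result is a
#' root-only tree (`no_tree = TRUE`), as happens for species whose
#' outcome the predictors do not structure.
#'
#' @param records Data frame of coded fish records.
#' @param response Response column name; coerced to factor (for survival,
#'   0 = dead, 1 = alive).
#' @param predictors Character vector of predictor columns (numeric or
#'   factor-like).
#' @param min_split Minimum node size eligible for splitting (default 20).
#' @param min_bucket Minimum child size (default `min_split %/% 3`).
#' @param cp Minimum impurity decrease relative to the root impurity
#'   (default 0.01).
#' @param max_depth Maximum tree depth (default 6).
#' @return Object of class `tree_fit`: `nodes` (data frame: id, n,
#'   coverage_pct, per-level proportions, label, split), `levels`,
#'   `no_tree` flag.
#' @export
fit_decision_tree <- function(records, response, predictors,
                              min_split = 20L, min_bucket = min_split %/% 3L,
                              cp = 0.01, max_depth = 6L) {
  data <- records[!is.na(records[[response]]), , drop = FALSE]
  for (v in predictors) {
    if (!is.numeric(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  y <- factor(data[[response]])
  data[[response]] <- y
  root_imp <- nrow(data) * gini_impurity(y)
  nodes <- grow_node(data, response, predictors, 1L, nrow(data),
                     max(root_imp, .Machine$double.eps),
                     min_split, min_bucket, cp, 0L, max_depth)
  prop_mat <- do.call(rbind, lapply(nodes, `[[`, "props"))
  colnames(prop_mat) <- paste0("p_", levels(y))
  tab <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    n = vapply(nodes, `[[`, integer(1), "n"),
    coverage_pct = vapply(nodes, `[[`, numeric(1), "coverage_pct"),
    prop_mat,
    label = vapply(nodes, `[[`, character(1), "label"),
    split = vapply(nodes, `[[`, character(1), "split_desc")
  )
  # dead/alive labels under the > 50% dead rule for a 0/1 survival response
  if (all(levels(y) %in% c("0", "1"))) {
    p0 <- if ("p_0" %in% colnames(prop_mat)) tab$p_0 else 0
    tab$label <- ifelse(p0 > 0.5, "Dead", "Alive")
  }
  tab <- tab[order(tab$id), ]
  rownames(tab) <- NULL
  structure(
    list(nodes = tab, frame = nodes, levels = levels(y),
         response = response, no_tree = nrow(tab) == 1L),
    class = "tree_fit"
  )
}

#' @export
print.tree_fit <- function(x, digits = 2, ...) {
  if (x$no_tree) {
    cat("<tree_fit> no tree could be developed (no admissible split);",
        "root label:", x$nodes$label[1L], "\n")
    return(invisible(x))
  }
  depth_of <- function(id) floor(log2(id))
  for (r in seq_len(nrow(x$nodes))) {
    nd <- x$nodes[r, ]
    indent <- strrep("  ", depth_of(nd$id))
    props <- round(unlist(nd[grep("^p_", names(nd))]), digits)
    cat(sprintf("%s[%d] %s n=%d (%.0f%%) props=(%s)%s\n",
                indent, nd$id, nd$label, nd$n, nd$coverage_pct,
                paste(props, collapse = ", "),
                if (!is.na(nd$split)) paste0(" split: ", nd$split) else ""))
  }
  invisible(x)
}

#' @export
predict.tree_fit <- function(object, newdata, ...) {
  walk <- function(row) {
    node <- object$frame[[1L]]
    by_id <- stats::setNames(object$frame,
                             vapply(object$frame, `[[`, integer(1), "id"))
    while (!is.null(node$children)) {
      x <- row[[node$split_var]]
      left <- if (is.na(x)) {
        by_id[[as.character(node$children[1L])]]$n >=
          by_id[[as.character(node$children[2L])]]$n
      } else if (!is.na(node$split_cut)) {
        x < node$split_cut
      } else {
        as.character(x) %in% node$split_levels
      }
      node <- by_id[[as.character(if (left) node$children[1L]
                                  else node$children[2L])]]
    }
    node$label
  }
  vapply(seq_len(nrow(newdata)), function(i) walk(newdata[i, , drop = FALSE]),
         character(1))
}
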