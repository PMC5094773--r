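#' Constraints for triage-model derivation
#'
#' The derivation maximises, step by step, the number of records resolved
#' (called high-risk or discharged) subject to a safety constraint on the
#' discharge side: the share of truly high-risk (GROUP2) women among all
#' discharge calls made so far must not exceed `max_false_low_risk_rate`.
#' An alternative reading of the constraint (`constraint_scope =
#' "group2_share"`: discharged GROUP2 women as a share of *all* GROUP2
#' women) is available. Optionally a symmetric purity constraint can be
#' placed on the high-risk side; by default it is off, matching the stated
#' derivation procedure.
#'
#' @param max_false_low_risk_rate Maximum GROUP2 share allowed among
#'   discharge calls (default 0.05).
#' @param constraint_scope `"discharge_share"` (default) or `"group2_share"`.
#' @param max_false_high_risk_rate Optional maximum GROUP1 share among
#'   high-risk calls per step; `NULL` disables it.
#' @param mm_grid,pct_grid Integer threshold grids searched, mm and percent.
#' @param tree_max_depth,tree_min_leaf Recursive-partitioning controls for
#'   the third step.
#' @return A `derivation_constraints` list.
#' @export
derivation_constraints <- function(max_false_low_risk_rate = 0.05,
                                   constraint_scope = c("discharge_share", "group2_share"),
                                   max_false_high_risk_rate = NULL,
                                   mm_grid = 10:50, pct_grid = 0:40,
                                   tree_max_depth = 3, tree_min_leaf = 10) {
  constraint_scope <- match.arg(constraint_scope)
  stopifnot(
    max_false_low_risk_rate > 0, max_false_low_risk_rate < 1,
    tree_max_depth >= 1, tree_min_leaf >= 1
  )
  structure(as.list(environment()), class = "derivation_constraints")
}

# feature frame used throughout derivation (pre-cerclage measurements only)
.derivation_features <- function(cohort) {
  cohort <- add_deltas(censor_post_cerclage(cohort))
  tibble::tibble(
    cl_a = cohort$cl_a, cl_b = cohort$cl_b, cl_c = cohort$cl_c,
    delta_ab = cohort$delta_ab, delta_bc = cohort$delta_bc,
    delta_ac = cohort$delta_ac
  )
}

# cumulative discharge-safety feasibility
.feasible <- function(n_d, g2_d, cons, n_g2_total) {
  if (cons$constraint_scope == "discharge_share") {
    g2_d <= cons$max_false_low_risk_rate * n_d
  } else {
    g2_d <= cons$max_false_low_risk_rate * n_g2_total
  }
}

# Step 1: exhaustive search of (a_high_lt, a_low_ge) on the mm grid.
# Objective: resolved count; ties -> largest discharge threshold (smallest
# discharge region), then smallest high threshold (smallest high region).
.step1_search <- function(cl_a, g2, cons, n_g2_total) {
  grid <- cons$mm_grid
  obs <- !is.na(cl_a)
  n_below <- vapply(grid, function(t) sum(obs & cl_a < t), 1L)
  g1_below <- vapply(grid, function(t) sum(obs & !g2 & cl_a < t), 1L)
  n_ge <- vapply(grid, function(t) sum(obs & cl_a >= t), 1L)
  g2_ge <- vapply(grid, function(t) sum(obs & g2 & cl_a >= t), 1L)

  best <- NULL
  for (j in seq_along(grid)) {      # t2 = discharge threshold
    if (!.feasible(n_ge[j], g2_ge[j], cons, n_g2_total)) next
    ii <- which(grid < grid[j])
    if (!is.null(cons$max_false_high_risk_rate)) {
      ii <- ii[g1_below[ii] <= cons$max_false_high_risk_rate * n_below[ii]]
    }
    if (!length(ii)) next
    i <- ii[which.max(n_below[ii])]   # first maximum = smallest high threshold
    cand <- c(resolved = n_below[i] + n_ge[j], t1 = grid[i], t2 = grid[j],
              n_d = n_ge[j], g2_d = g2_ge[j], n_h = n_below[i])
    if (is.null(best) ||
        cand[["resolved"]] > best[["resolved"]] ||
        (cand[["resolved"]] == best[["resolved"]] && cand[["t2"]] > best[["t2"]]) ||
        (cand[["resolved"]] == best[["resolved"]] && cand[["t2"]] == best[["t2"]] &&
         cand[["t1"]] < best[["t1"]])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    warning("step 1: no threshold pair resolves any record under the constraint; ",
            "returning degenerate thresholds", call. = FALSE)
    best <- c(resolved = 0, t1 = min(grid), t2 = max(grid), n_d = 0, g2_d = 0,
              n_h = 0)
  }
  best
}

# 2-D cumulative count matrix: entry (i, j) = #(x < xgrid[i] & y < ygrid[j]).
# Integer grids, so findInterval(v, grid) < i  <=>  v < grid[i].
.cum2 <- function(x, y, xgrid, ygrid) {
  nm <- length(xgrid)
  np <- length(ygrid)
  tab <- matrix(0L, nm + 1L, np + 1L)
  if (length(x)) {
    ix <- pmin(findInterval(x, xgrid) + 1L, nm + 1L)
    iy <- pmin(findInterval(y, ygrid) + 1L, np + 1L)
    for (k in seq_along(x)) tab[ix[k], iy[k]] <- tab[ix[k], iy[k]] + 1L
  }
  cs <- t(apply(apply(tab, 2, cumsum), 1, cumsum))
  cs[seq_len(nm), seq_len(np), drop = FALSE]
}

# Step 2: search (b_high_cl_lt, b_high_delta_ge, b_low_cl_ge,
# b_low_delta_lt) on records still CONTINUE. Counts come from 2-D
# cumulative histograms so each quadruple is O(1). Clauses with a missing
# operand are inert; records missing cl_b stay CONTINUE.
.step2_search <- function(cl_b, d_ab, g2, cons, carry_n_d, carry_g2_d,
                          n_g2_total) {
  gm <- cons$mm_grid
  gp <- cons$pct_grid
  nm <- length(gm)
  np <- length(gp)

  both <- !is.na(cl_b) & !is.na(d_ab)
  only <- !is.na(cl_b) & is.na(d_ab)

  C_all <- .cum2(cl_b[both], d_ab[both], gm, gp)
  C_g2 <- .cum2(cl_b[both & g2], d_ab[both & g2], gm, gp)
  T_all <- vapply(gp, function(t) sum(both & d_ab < t), 1L)
  T_g2 <- vapply(gp, function(t) sum(both & g2 & d_ab < t), 1L)
  n1_below <- vapply(gm, function(t) sum(only & cl_b < t), 1L)
  g2_1_below <- vapply(gm, function(t) sum(only & g2 & cl_b < t), 1L)
  n1 <- sum(only)
  g2_1 <- sum(only & g2)
  n2 <- sum(both)
  g2_2 <- sum(both & g2)

  lq <- expand.grid(l1 = seq_len(nm), l2 = seq_len(np))
  l1i <- lq$l1
  l2j <- lq$l2

  best <- NULL
  for (i1 in seq_len(nm)) {        # h1 index: b_high_cl_lt
    for (j2 in seq_len(np)) {      # h2 index: b_high_delta_ge
      A_all <- T_all[j2] - C_all[i1, j2]   # not-high among 'both'
      A_g2 <- T_g2[j2] - C_g2[i1, j2]
      n_h <- (n2 - A_all) + n1_below[i1]
      # discharge among 'both' = not-high minus the still-continue box
      # cl_b in [h1, l1) x d_ab in [l2, h2)
      in_box <- l1i > i1 & j2 > l2j
      box <- ifelse(in_box,
                    C_all[cbind(l1i, j2)] - C_all[i1, j2] -
                      C_all[cbind(l1i, l2j)] +
                      C_all[cbind(rep(i1, length(l2j)), l2j)],
                    0L)
      box_g2 <- ifelse(in_box,
                       C_g2[cbind(l1i, j2)] - C_g2[i1, j2] -
                         C_g2[cbind(l1i, l2j)] +
                         C_g2[cbind(rep(i1, length(l2j)), l2j)],
                       0L)
      D2 <- A_all - box
      D2_g2 <- A_g2 - box_g2
      # among 'only': high iff cl_b < h1; the rest discharge iff cl_b >= l1
      D1 <- ifelse(l1i <= i1, n1 - n1_below[i1],
                   n1 - pmax(n1_below[l1i], n1_below[i1]))
      D1_g2 <- ifelse(l1i <= i1, g2_1 - g2_1_below[i1],
                      g2_1 - pmax(g2_1_below[l1i], g2_1_below[i1]))
      n_d <- D2 + D1
      g2_d <- D2_g2 + D1_g2
      # model invariant: the discharge CL threshold must exceed the high one
      ok <- l1i > i1 &
        .feasible(carry_n_d + n_d, carry_g2_d + g2_d, cons, n_g2_total)
      if (!is.null(cons$max_false_high_risk_rate) && n_h > 0) {
        g2_h <- (g2_2 - A_g2) + g2_1_below[i1]
        ok <- ok & ((n_h - g2_h) <= cons$max_false_high_risk_rate * n_h)
      }
      if (!any(ok)) next
      resolved <- n_h + n_d
      resolved[!ok] <- -1L
      k <- order(-resolved, n_d, -l1i, l2j)[1]
      if (resolved[k] < 0) next
      cand <- list(resolved = resolved[k], h1 = gm[i1], h2 = gp[j2],
                   l1 = gm[l1i[k]], l2 = gp[l2j[k]],
                   n_d = n_d[k], g2_d = g2_d[k], n_h = n_h)
      if (is.null(best) ||
          cand$resolved > best$resolved ||
          (cand$resolved == best$resolved && cand$n_d < best$n_d)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    warning("step 2: constraint infeasible for every threshold quadruple; ",
            "returning degenerate thresholds", call. = FALSE)
    best <- list(resolved = 0, h1 = min(gm), h2 = max(gp), l1 = max(gm),
                 l2 = min(gp), n_d = 0, g2_d = 0, n_h = 0)
  }
  best
}

# Step 3: recursive partitioning (Gini) on the records still under
# surveillance; leaves are then greedily discharged in order of GROUP2
# purity while the cumulative discharge constraint holds. Leaves tied on
# purity are admitted or refused together.
.step3_tree <- function(feats, g2, cons, carry_n_d, carry_g2_d, n_g2_total) {
  empty <- list(tree = NULL, p_cut = -Inf, n_d = 0L, g2_d = 0L, const = NULL)
  if (nrow(feats) == 0) return(empty)
  if (length(unique(g2)) == 1) {
    # a single outcome class: no split is informative, one terminal leaf
    if (.feasible(carry_n_d + length(g2), carry_g2_d + sum(g2), cons,
                  n_g2_total)) {
      return(list(tree = NULL, p_cut = 1, n_d = length(g2),
                  g2_d = sum(g2), const = "DISCHARGE"))
    }
    return(list(tree = NULL, p_cut = -Inf, n_d = 0L, g2_d = 0L,
                const = "HIGH_RISK"))
  }
  df <- dplyr::mutate(feats, .y = factor(ifelse(g2, "g2", "g1"),
                                         levels = c("g1", "g2")))
  fit <- rpart::rpart(
    .y ~ cl_a + cl_b + cl_c + delta_ab + delta_bc + delta_ac,
    data = df, method = "class", parms = list(split = "gini"),
    control = rpart::rpart.control(
      maxdepth = cons$tree_max_depth, minbucket = cons$tree_min_leaf,
      minsplit = 2 * cons$tree_min_leaf, cp = 0, xval = 0,
      maxcompete = 0, maxsurrogate = 0
    )
  )
  leaf_tab <- tibble::tibble(leaf = fit$where, g2 = g2) |>
    dplyr::group_by(.data$leaf) |>
    dplyr::summarise(n = dplyr::n(), n_g2 = sum(.data$g2),
                     p_g2 = mean(.data$g2), .groups = "drop") |>
    dplyr::arrange(.data$p_g2)

  p_cut <- -Inf
  n_d <- carry_n_d
  g2_d <- carry_g2_d
  for (p in unique(leaf_tab$p_g2)) {
    tie <- leaf_tab$p_g2 == p
    add_n <- sum(leaf_tab$n[tie])
    add_g2 <- sum(leaf_tab$n_g2[tie])
    if (.feasible(n_d + add_n, g2_d + add_g2, cons, n_g2_total)) {
      p_cut <- p
      n_d <- n_d + add_n
      g2_d <- g2_d + add_g2
    } else {
      break
    }
  }
  list(tree = fit, p_cut = p_cut, n_d = n_d - carry_n_d,
       g2_d = g2_d - carry_g2_d)
}

# best-effort: read Fig-3-shaped step-C thresholds off the tree's primary
# splits (informational; prediction uses the tree itself)
.extract_c_rules <- function(fit, model) {
  if (is.null(fit$splits) || !nrow(fit$splits)) return(model)
  pick <- function(var) {
    rows <- which(rownames(fit$splits) == var)
    if (length(rows)) unname(fit$splits[rows[1], "index"]) else NA_real_
  }
  v <- pick("cl_c")
  if (!is.na(v)) model$c_rule2_c_le <- v
  v <- pick("cl_a")
  if (!is.na(v)) model$c_rule1_a_lt <- v
  v <- pick("cl_b")
  if (!is.na(v)) model$c_rule3_b_lt <- v
  model
}

# Leaf membership is recovered through the leaf's training purity: the
# predicted class probability for new data equals the leaf's GROUP2 fraction.
.rpart_discharge <- function(fit, p_cut, newdata) {
  p <- stats::predict(fit, newdata = newdata, type = "prob")[, "g2"]
  p <= p_cut
}

#' Derive a triage model from a labelled cohort
#'
#' Reconstructs the three-step derivation: (1) exhaustive grid search of the
#' step-A threshold pair maximising resolved records under the cumulative
#' discharge-safety constraint; (2) grid search of the step-B high/discharge
#' threshold quadruple on the records still under surveillance; (3) a
#' recursive-partitioning classifier (Gini splits on CL at A/B/C and the
#' three interval changes) whose leaves are discharged in order of GROUP2
#' purity while the constraint holds. Validation is leave-one-hospital-out:
#' the model is derived on all sites but one and evaluated on the held-out
#' site, reporting GROUP2 sensitivity and the false-low-risk rate (GROUP2
#' share among low-risk calls) per fold.
#'
#' @param cohort A cohort tibble with `hospital` and outcome fields; risk
#'   groups are assigned if absent. At least two hospitals are required.
#' @param constraints A [derivation_constraints()].
#' @param validate Run leave-one-hospital-out validation (default `TRUE`).
#' @return A `derived_triage_model` (usable anywhere a [triage_model()] is)
#'   with `derivation` (per-step resolution counts) and `validation`
#'   (per-fold tibble) components. The step-C stage carries the fitted
#'   tree; Fig-3-shaped step-C thresholds are extracted from its top splits
#'   where the structure allows.
#' @export
derive_triage_model <- function(cohort, constraints = derivation_constraints(),
                                validate = TRUE) {
  stopifnot(inherits(constraints, "derivation_constraints"))
  if (!"risk_group" %in% names(cohort)) cohort <- add_risk_group(cohort)
  hospitals <- unique(cohort$hospital)
  if (length(hospitals) < 2) {
    stop("derivation requires records from at least two hospitals",
         call. = FALSE)
  }

  fit_one <- function(data) {
    feats <- .derivation_features(data)
    g2 <- data$risk_group == "GROUP2"
    n_g2 <- sum(g2)

    s1 <- .step1_search(feats$cl_a, g2, constraints, n_g2)
    dec_a <- classify_timepoint_a(
      feats$cl_a, triage_model(a_high_lt = s1[["t1"]], a_low_ge = s1[["t2"]])
    )
    open <- dec_a == "CONTINUE"

    s2 <- .step2_search(feats$cl_b[open], feats$delta_ab[open], g2[open],
                        constraints, s1[["n_d"]], s1[["g2_d"]], n_g2)
    m12 <- triage_model(
      a_high_lt = s1[["t1"]], a_low_ge = s1[["t2"]],
      b_high_cl_lt = s2$h1, b_high_delta_ge = s2$h2,
      b_low_cl_ge = s2$l1, b_low_delta_lt = s2$l2
    )
    dec_b <- rep(NA_character_, nrow(data))
    dec_b[open] <- classify_timepoint_b(feats$cl_a[open], feats$cl_b[open], m12)
    open_c <- open & dec_b == "CONTINUE"

    s3 <- .step3_tree(feats[open_c, , drop = FALSE], g2[open_c], constraints,
                      s1[["n_d"]] + s2$n_d, s1[["g2_d"]] + s2$g2_d, n_g2)
    model <- m12
    if (!is.null(s3$tree)) {
      model <- .extract_c_rules(s3$tree, model)
      model$step3_tree <- s3$tree
      model$step3_p_cut <- s3$p_cut
    } else if (!is.null(s3$const)) {
      model$step3_const <- s3$const
    }
    model$derivation <- tibble::tibble(
      step = c("A", "B", "C"),
      n_entering = c(nrow(data), sum(open), sum(open_c)),
      n_high = c(s1[["n_h"]], s2$n_h, sum(open_c) - s3$n_d),
      n_discharged = c(s1[["n_d"]], s2$n_d, s3$n_d),
      g2_discharged = c(s1[["g2_d"]], s2$g2_d, s3$g2_d)
    )
    class(model) <- c("derived_triage_model", "triage_model")
    model
  }

  model <- fit_one(cohort)

  if (validate) {
    model$validation <- purrr::map_dfr(sort(hospitals), function(h) {
      train <- cohort[cohort$hospital != h, , drop = FALSE]
      test <- cohort[cohort$hospital == h, , drop = FALSE]
      fold_model <- fit_one(train)
      out <- run_triage(test, fold_model)
      low <- out$final %in% c("DISCHARGE", "COMPLETED")
      g2 <- test$risk_group == "GROUP2"
      tibble::tibble(
        held_out = h, n_test = nrow(test),
        n_low_calls = sum(low),
        sensitivity = if (any(g2)) mean(out$final[g2] == "HIGH_RISK") else NA_real_,
        false_low_risk_rate = if (any(low)) mean(g2[low]) else 0
      )
    })
  }
  model
}

#' @rdname derive_triage_model
#' @param x A `derived_triage_model`.
#' @param ... Unused.
#' @method glance derived_triage_model
#' @export
glance.derived_triage_model <- function(x, ...) {
  v <- x$validation
  tibble::tibble(
    n_derivation = x$derivation$n_entering[1],
    resolved_step_a = x$derivation$n_high[1] + x$derivation$n_discharged[1],
    resolved_step_b = x$derivation$n_high[2] + x$derivation$n_discharged[2],
    discharged_total = sum(x$derivation$n_discharged),
    g2_discharged_total = sum(x$derivation$g2_discharged),
    folds = if (is.null(v)) 0L else nrow(v),
    mean_fold_sensitivity = if (is.null(v)) NA_real_ else mean(v$sensitivity, na.rm = TRUE),
    max_fold_false_low_risk = if (is.null(v)) NA_real_ else max(v$false_low_risk_rate)
  )
}
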