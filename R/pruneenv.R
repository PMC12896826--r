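#' FLOPs budget for the pruning search
#'
#' The search maximizes post-pruning accuracy subject to
#' `pruned MACs / original MACs <= R_target`, with every coupling group
#' floored at a minimum channel retention so no layer collapses.
#'
#' @param R_target target MAC ratio in (0, 1].
#' @param original_macs total MACs of the unpruned model.
#' @param r_min minimum per-group channel retention (default 0.2).
#' @return a `prune_budget` list.
#' @export
prune_budget <- function(R_target, original_macs, r_min = 0.2) {
  stopifnot(R_target > 0, R_target <= 1, original_macs > 0,
            r_min > 0, r_min <= 1)
  structure(list(R_target = R_target, original_macs = original_macs,
                 r_min = r_min), class = "prune_budget")
}

# Total MACs as a function of the five group kept-counts, matching
# count_macs() on the corresponding spec (verified by test).
# w: named widths as in build_sresnet(); L: input length; C: classes.
.macs_widths <- function(w, L, C, fc1_out = 64L) {
  conv <- function(out, inp, k) out * inp * k * L + out * L
  conv(w[1], 1, 3) +
    conv(w[2], w[1], 3) + conv(w[3], w[2], 3) + conv(w[3], w[1], 1) +
    conv(w[4], w[3], 3) + conv(w[5], w[4], 3) + conv(w[5], w[3], 1) +
    (fc1_out * w[5] + fc1_out) + (C * fc1_out + C)
}

.kept_count <- function(R, c_in, r_min)
  min(max(ceiling(R * c_in), ceiling(r_min * c_in)), c_in)

# last decision group that touches each weighted layer; fc2 is never pruned
.layer_group <- c(conv1 = 1L, b1_conva = 2L, b1_convb = 3L, b1_short = 3L,
                  b2_conva = 4L, b2_convb = 5L, b2_short = 5L,
                  fc1 = 5L, fc2 = 0L)

#' Clamp a proposed retention to the FLOPs budget
#'
#' Returns `min(proposed, R_max)` where `R_max` is the largest retention
#' for the current group such that pruning every remaining group at the
#' minimum retention still satisfies the budget. The result never drops
#' below `r_min`. This bounded-action scheme guarantees the constraint
#' holds at episode end without ever aborting mid-episode.
#'
#' @param budget a [prune_budget()].
#' @param spec0 the *unpruned* `model_spec` (defines group widths).
#' @param decided integer vector of kept counts for groups already
#'   decided (possibly empty).
#' @param proposed proposed retention for the next group.
#' @return clamped retention rate.
#' @export
feasible_action <- function(budget, spec0, decided, proposed) {
  groups <- coupling_groups(spec0)
  nG <- length(groups)
  l <- length(decided) + 1L
  if (l > nG) stop("all groups already decided")
  cin <- vapply(groups, `[[`, 0L, "c_in")
  kmin <- ceiling(budget$r_min * cin)
  limit <- budget$R_target * budget$original_macs
  widths_for <- function(k_l)
    c(decided, k_l, if (l < nG) kmin[(l + 1L):nG])
  L <- spec0$input_length; C <- spec0$num_classes
  if (.macs_widths(widths_for(kmin[l]), L, C, spec0$layers$fc1$out_ch) > limit)
    stop("budget infeasible: even minimum retentions exceed the target ratio")
  k_max <- kmin[l]
  for (k in seq(kmin[l], cin[l])) {
    if (.macs_widths(widths_for(k), L, C, spec0$layers$fc1$out_ch) <= limit)
      k_max <- k else break
  }
  R_max <- k_max / cin[l]
  max(min(proposed, R_max), budget$r_min)
}

#' Per-channel state matrix for a pruning decision
#'
#' One row per input channel of the group, with eleven entries:
#' group index `l`, layer-type code `t` (1 conv, 2 fc), `c_in`, `c_out`,
#' `stride`, `k` (all from the group's first consumer), the channel's
#' parameter count `Wprod` and weight L2 norm `Wnorm`, the MACs already
#' removed by earlier decisions (`reduced`), the MACs of layers whose
#' cost is still undecided (`rest`), and the previous group's retention
#' `R_prev` (1 for the first group). A fully connected consumer is
#' described with `k = 1`, stride 1.
#'
#' @param model current (partially pruned) `sresnet_model`.
#' @param group one element of [coupling_groups()] for the current spec.
#' @param reduced,rest MAC bookkeeping for the episode so far.
#' @param R_prev retention chosen for the previous group.
#' @return numeric matrix `c_in x 11` with named columns.
#' @export
layer_state <- function(model, group, reduced, rest, R_prev) {
  first <- model$spec$layers[[group$consumers[1]]]
  S <- channel_slices(model, group)
  M <- nrow(S)
  st <- cbind(l = group$index,
              t = if (first$kind == "conv1d") 1 else 2,
              c_in = first$in_ch, c_out = first$out_ch,
              stride = first$stride, k = first$k,
              Wprod = ncol(S), Wnorm = sqrt(rowSums(S^2)),
              reduced = reduced, rest = rest, R_prev = R_prev)
  rownames(st) <- NULL
  st
}

# column-wise min-max scaling bounds computed once per episode from the
# unpruned model; dynamic columns use their a-priori ranges
.state_bounds <- function(model, groups, total_macs) {
  states <- lapply(groups, function(g) layer_state(model, g, 0, 0, 1))
  all <- do.call(rbind, states)
  lo <- apply(all, 2, min); hi <- apply(all, 2, max)
  lo["reduced"] <- 0; hi["reduced"] <- total_macs
  lo["rest"] <- 0; hi["rest"] <- total_macs
  lo["R_prev"] <- 0; hi["R_prev"] <- 1
  list(lo = lo, hi = hi)
}

.scale_state <- function(st, bounds) {
  rng <- pmax(bounds$hi - bounds$lo, 1e-12)
  sweep(sweep(st, 2, bounds$lo), 2, rng, "/")
}

#' Markov decision process environment for channel pruning
#'
#' Wraps a trained model as a finite-horizon environment: each step
#' presents the per-channel state of one coupling group (as a channel
#' graph, see [build_channel_graph()]), accepts a retention action,
#' clamps it to the FLOPs budget via [feasible_action()], prunes the
#' group by L2-norm importance, and on the final group returns the
#' terminal reward `accuracy x reward_scale` measured on `eval_set`
#' (0 when no evaluation set is supplied). Intermediate rewards are 0.
#'
#' @param model trained `sresnet_model` (the unpruned reference).
#' @param budget a [prune_budget()]; its `original_macs` must equal the
#'   model's MAC total.
#' @param eval_set held-out [herd_dataset()] for the terminal reward, or
#'   `NULL` to skip reward evaluation.
#' @param reward_scale terminal reward is accuracy times this scale
#'   (default 0.01).
#' @param k_nn neighbor count for the channel graph.
#' @return a `prune_env` list of closures: `reset()` returning the first
#'   state, `step(R)` returning
#'   `list(state, action, reward, next_state, done)`, `result()`
#'   returning the episode's `prune_result`, and `n_groups`.
#' @export
prune_env <- function(model, budget, eval_set = NULL, reward_scale = 0.01,
                      k_nn = 5) {
  stopifnot(inherits(model, "sresnet_model"), inherits(budget, "prune_budget"))
  spec0 <- model$spec
  groups0 <- coupling_groups(spec0)
  nG <- length(groups0)
  total <- count_macs(spec0)$total
  if (budget$original_macs != total)
    stop("budget original_macs (", budget$original_macs,
         ") does not match the model (", total, ")")
  # fail fast if even the all-minimum strategy cannot meet the target
  feasible_action(budget, spec0, integer(0), budget$r_min)
  bounds <- .state_bounds(model, groups0, total)
  lg <- .layer_group
  cur <- NULL; l <- NA_integer_; decided <- integer(0)
  kept <- list(); retention <- numeric(0); state <- NULL; done <- TRUE
  rest_of <- function(m, li) {
    per <- count_macs(m$spec)$per_layer
    sum(per$macs[lg[per$layer] > li])
  }
  build_state <- function(m, li, R_prev) {
    gr <- coupling_groups(m$spec)[[li]]
    reduced <- total - count_macs(m$spec)$total
    st <- layer_state(m, gr, reduced, rest_of(m, li), R_prev)
    build_channel_graph(.scale_state(st, bounds), channel_slices(m, gr),
                        k_nn = k_nn)
  }
  reset <- function() {
    cur <<- model; l <<- 1L; decided <<- integer(0)
    kept <<- list(); retention <<- numeric(0); done <<- FALSE
    state <<- build_state(cur, 1L, 1)
    state
  }
  step <- function(R) {
    if (done) stop("episode finished; call reset()")
    a <- feasible_action(budget, spec0, decided, R)
    gr <- coupling_groups(cur$spec)[[l]]
    pr <- prune_group(cur, gr, a, budget$r_min)
    cur <<- pr$model
    kept[[l]] <<- pr$kept
    retention[l] <<- length(pr$kept) / gr$c_in
    decided <<- c(decided, length(pr$kept))
    s_prev <- state
    if (l == nG) {
      done <<- TRUE
      acc <- if (is.null(eval_set)) NA_real_ else model_accuracy(cur, eval_set)
      reward <- if (is.na(acc)) 0 else acc * reward_scale
      state <<- NULL
      list(state = s_prev, action = a, reward = reward, next_state = NULL,
           done = TRUE, accuracy = acc)
    } else {
      l <<- l + 1L
      state <<- build_state(cur, l, retention[l - 1L])
      list(state = s_prev, action = a, reward = 0, next_state = state,
           done = FALSE, accuracy = NA_real_)
    }
  }
  result <- function() {
    if (!done) stop("episode not finished")
    after <- count_macs(cur$spec)
    structure(list(retention = retention, kept = kept, spec = cur$spec,
                   model = cur, macs_before = count_macs(spec0),
                   macs_after = after, mac_ratio = after$total / total),
              class = "prune_result")
  }
  structure(list(reset = reset, step = step, result = result, n_groups = nG,
                 original_macs = total, budget = budget),
            class = "prune_env")
}

#' Run one pruning episode under a policy
#'
#' Iterates the coupling groups in order, querying `policy` for each
#' state, and returns the pruned model, bookkeeping and the transition
#' tuples (state graph, clamped action, reward, next state, terminal
#' flag) for replay.
#'
#' @param env a [prune_env()] (or any object with the same contract).
#' @param policy function `(state, group_index) -> retention proposal`.
#' @return list with `result` (a `prune_result` carrying the terminal
#'   `reward` and `accuracy`) and `transitions`.
#' @export
run_prune_episode <- function(env, policy) {
  s <- env$reset()
  transitions <- vector("list", env$n_groups)
  reward <- 0; acc <- NA_real_
  for (l in seq_len(env$n_groups)) {
    out <- env$step(policy(s, l))
    transitions[[l]] <- out
    s <- out$next_state
    if (out$done) { reward <- out$reward; acc <- out$accuracy }
  }
  res <- env$result()
  res$reward <- reward
  res$accuracy <- acc
  list(result = res, transitions = transitions)
}

#' @export
print.prune_result <- function(x, ...) {
  cat("prune_result: MAC ratio", round(x$mac_ratio, 4),
      sprintf("(%.3fM -> %.3fM)\n", x$macs_before$total / 1e6,
              x$macs_after$total / 1e6))
  cat("  retentions:", paste(round(x$retention, 3), collapse = ", "), "\n")
  if (!is.null(x$accuracy) && !is.na(x$accuracy))
    cat("  accuracy:", round(x$accuracy, 4), " reward:", x$reward, "\n")
  invisible(x)
}

#' Serialize a pruning result to JSON
#' @param x a `prune_result`.
#' @param path optional output file.
#' @return JSON string, or `path` invisibly when writing to file.
#' @export
prune_result_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(list(
    retention = x$retention, kept = x$kept,
    widths = as.list(spec_widths(x$spec)),
    mac_ratio = x$mac_ratio,
    macs_before = x$macs_before$total, macs_after = x$macs_after$total,
    reward = x$reward, accuracy = x$accuracy),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
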