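#' Parameters of the gene gain/loss process
#'
#' Each gene family evolves independently along the tree as a two-state
#' continuous-time Markov chain: absent -> present at rate `gain` and
#' present -> absent at rate `loss` (events per family per unit branch
#' length). The root state is Bernoulli with probability
#' `root_presence_prob`, which defaults to the stationary probability
#' `gain / (gain + loss)` so the process is stationary unless overridden.
#'
#' @param gain,loss non-negative rates; at least one must be positive
#'   unless `root_presence_prob` is given explicitly.
#' @param n_families positive integer, number of independent families.
#' @param root_presence_prob probability in `[0, 1]` or `NULL` for the
#'   stationary default.
#' @param master_seed integer master seed; per-family and per-branch
#'   streams are derived from it deterministically.
#' @return an object of class `gain_loss_params`.
#' @export
gain_loss_params <- function(gain, loss, n_families,
                             root_presence_prob = NULL,
                             master_seed = 1L) {
  if (gain < 0 || loss < 0) stop("rates must be non-negative")
  n_families <- as.integer(n_families)
  if (is.na(n_families) || n_families < 1L)
    stop("n_families must be a positive integer")
  if (is.null(root_presence_prob)) {
    if (gain + loss <= 0)
      stop("gain + loss = 0: stationary root probability undefined; ",
           "set root_presence_prob explicitly")
    root_presence_prob <- gain / (gain + loss)
  }
  if (root_presence_prob < 0 || root_presence_prob > 1)
    stop("root_presence_prob must be in [0, 1]")
  structure(list(gain = gain, loss = loss, n_families = n_families,
                 root_presence_prob = root_presence_prob,
                 master_seed = as.integer(master_seed)),
            class = "gain_loss_params")
}

#' Evolve gene-family presence/absence along a tree
#'
#' Simulates, for every family, the exact event history (Gillespie
#' algorithm: exponential waiting times between state flips) along each
#' branch in preorder, and records leaf presence states plus a replayable
#' event trace. Each (family, branch) pair uses its own seed derived from
#' the master seed, so results do not depend on evaluation order.
#'
#' @param tree an [sample_tree()] `evol_tree` (or an ape phylo).
#' @param params a [gain_loss_params()].
#' @return an object of class `content_truth`: a list with `matrix`
#'   (taxa x families 0/1 integer matrix), `trace` (data.frame `family`,
#'   `branch` = preorder edge index, `child` = child node label where
#'   available, `event` in gain/loss, `position` = distance from the
#'   parent end of the branch), `root_states`, and `params`.
#' @export
evolve_content <- function(tree, params) {
  stopifnot(inherits(params, "gain_loss_params"))
  phy <- if (inherits(tree, "evol_tree")) tree$phy else tree
  edges <- tree_edges_preorder(phy)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  fam_ids <- sprintf("F%04d", seq_len(params$n_families))
  mat <- matrix(0L, nrow = ntip, ncol = params$n_families,
                dimnames = list(phy$tip.label, fam_ids))
  acc <- vector("list", params$n_families)
  for (f in seq_len(params$n_families)) {
    state <- integer(nnode)
    state[root] <- with_seed(
      derive_seed(params$master_seed, f, 0L),
      rbinom(1L, 1L, params$root_presence_prob))
    fam_acc <- list()
    for (e in seq_len(nrow(edges))) {
      s <- state[edges$parent[e]]
      len <- edges$length[e]
      if (len > 0 && params$gain + params$loss > 0) {
        evs <- with_seed(
          derive_seed(params$master_seed, f, e),
          gillespie_branch(s, len, params$gain, params$loss))
        if (length(evs$pos))
          fam_acc[[length(fam_acc) + 1L]] <-
            list(branch = rep.int(e, length(evs$pos)),
                 event = evs$event, pos = evs$pos)
        s <- evs$state
      }
      state[edges$child[e]] <- s
    }
    if (length(fam_acc))
      acc[[f]] <- list(
        fam = rep.int(f, sum(lengths(lapply(fam_acc, `[[`, "pos")))),
        branch = unlist(lapply(fam_acc, `[[`, "branch")),
        event = unlist(lapply(fam_acc, `[[`, "event")),
        pos = unlist(lapply(fam_acc, `[[`, "pos")))
    mat[, f] <- state[seq_len(ntip)]
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  tr_fam <- unlist(lapply(acc, `[[`, "fam"))
  tr_branch <- unlist(lapply(acc, `[[`, "branch"))
  tr_event <- unlist(lapply(acc, `[[`, "event"))
  tr_pos <- unlist(lapply(acc, `[[`, "pos"))
  if (is.null(tr_fam)) {
    tr_fam <- integer(0); tr_branch <- integer(0)
    tr_event <- character(0); tr_pos <- numeric(0)
  }
  node_lab <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  trace <- data.frame(
    family = fam_ids[tr_fam], branch = tr_branch,
    child = node_lab[edges$child[tr_branch]],
    event = tr_event, position = tr_pos, stringsAsFactors = FALSE)
  structure(list(matrix = mat, trace = trace,
                 root_states = NULL, params = params, edges = edges),
            class = "content_truth")
}

# exact two-state event history along one branch
gillespie_branch <- function(state, len, gain, loss) {
  pos <- numeric(0); event <- character(0)
  t <- 0
  repeat {
    rate <- if (state == 0L) gain else loss
    if (rate <= 0) break
    t <- t + rexp(1L, rate)
    if (t >= len) break
    state <- 1L - state
    pos <- c(pos, t)
    event <- c(event, if (state == 1L) "gain" else "loss")
  }
  list(state = state, pos = pos, event = event)
}

#' Replay a gain/loss event trace from the root states
#'
#' Reconstructs leaf presence states by applying the recorded events along
#' each branch in preorder; used to check that the simulator's matrix and
#' trace are mutually consistent.
#'
#' @param tree the tree the trace was generated on.
#' @param truth a [evolve_content()] `content_truth`.
#' @return taxa x families 0/1 integer matrix.
#' @export
replay_trace <- function(tree, truth) {
  stopifnot(inherits(truth, "content_truth"))
  phy <- if (inherits(tree, "evol_tree")) tree$phy else tree
  edges <- tree_edges_preorder(phy)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  fam_ids <- colnames(truth$matrix)
  mat <- matrix(0L, nrow = ntip, ncol = length(fam_ids),
                dimnames = dimnames(truth$matrix))
  # root state per family: leaf state minus net flips cannot be read off
  # directly, so recover it from the stored simulation parameters
  for (fi in seq_along(fam_ids)) {
    tr <- truth$trace[truth$trace$family == fam_ids[fi], , drop = FALSE]
    root_state <- with_seed(
      derive_seed(truth$params$master_seed, fi, 0L),
      rbinom(1L, 1L, truth$params$root_presence_prob))
    state <- integer(ntip + phy$Nnode)
    state[root] <- root_state
    for (e in seq_len(nrow(edges))) {
      nflip <- sum(tr$branch == e)
      state[edges$child[e]] <- (state[edges$parent[e]] + nflip) %% 2L
    }
    mat[, fi] <- state[seq_len(ntip)]
  }
  mat
}
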