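#' Select co-reported terms by event-event disproportionality
#'
#' Within the reports carrying at least one drug of a pharmacological class
#' (as suspect or interacting), each preferred term is tested for
#' disproportionate co-reporting with the index condition: a 2x2 of (term
#' present) x (report is an index case) over the class reports, flagged when
#' the IC lower bound exceeds 0. The index condition's own terms are
#' excluded from the candidates. These selected terms are the nodes of the
#' symptom networks.
#'
#' @param db an `icsr_db`.
#' @param class_tag dictionary class tag (e.g. `"beta_blocker"`).
#' @param rp_case_ids ids of the index-condition case reports.
#' @param exclude_pts terms never selected (default: the terms defining the
#'   cases found in `rp_case_ids`... supply explicitly for clarity).
#' @param level credibility level.
#' @param min_obs minimum co-occurrence count for a term to be considered.
#' @return data.table of selected terms with their 2x2 margins and IC
#'   statistics (possibly zero rows, with a warning if the class has no
#'   cases).
#' @export
select_terms <- function(db, class_tag, rp_case_ids, exclude_pts = character(0),
                         level = 0.95, min_obs = 3L) {
  class_drugs <- .class_drugs(db$drug_dict, class_tag)
  if (length(class_drugs) == 0L) stop("no drug carries class tag: ", class_tag)
  class_reports <- unique(db$report_drugs[drug_id %in% class_drugs &
                                            role %in% c("suspect", "interacting"),
                                          report_id])
  cases <- intersect(class_reports, rp_case_ids)
  if (length(cases) == 0L) {
    warning("class ", class_tag, " has no index-condition cases")
    return(data.table(pt_code = character(), O = integer(), n_pt = integer(),
                      n_case = integer(), N = integer(), E = numeric(),
                      IC = numeric(), IC_LB = numeric()))
  }
  ev <- unique(db$report_events[report_id %in% class_reports,
                                .(report_id, pt_code)])
  ev <- ev[!pt_code %in% exclude_pts]
  N <- length(class_reports)
  n_case <- length(cases)
  tab <- ev[, .(n_pt = .N, O = sum(report_id %in% cases)), by = pt_code]
  tab <- tab[O >= min_obs]
  tab[, N := N]
  tab[, n_case := n_case]
  tab[, E := n_pt * n_case / N]
  tab[, IC := ic_point(O, E)]
  tab[, IC_LB := ic_lower_bound(O, E, level = level)]
  tab[IC_LB > 0][order(-IC_LB)]
}

.class_drugs <- function(drug_dict, class_tag) {
  dd <- as.data.table(drug_dict)
  tags <- strsplit(dd$class_tags, ";", fixed = TRUE)
  dd$drug_id[vapply(tags, function(tt) class_tag %in% tt, logical(1))]
}

#' Build the binary case-by-term matrix for a drug class
#'
#' Rows are the index-condition case reports carrying a class drug, columns
#' the selected preferred terms; entries indicate term presence (binary,
#' regardless of how many matching event entries a report has). Columns with
#' zero variance are dropped with a warning, since they carry no association
#' information.
#'
#' @param db an `icsr_db`.
#' @param class_tag drug class tag.
#' @param rp_case_ids index-condition case ids.
#' @param pt_codes selected terms (e.g. from [select_terms()]).
#' @return integer matrix with report ids as rownames.
#' @export
build_case_term_matrix <- function(db, class_tag, rp_case_ids, pt_codes) {
  stopifnot(length(pt_codes) >= 1L)
  class_drugs <- .class_drugs(db$drug_dict, class_tag)
  class_reports <- unique(db$report_drugs[drug_id %in% class_drugs &
                                            role %in% c("suspect", "interacting"),
                                          report_id])
  cases <- sort(intersect(class_reports, rp_case_ids))
  ev <- unique(db$report_events[report_id %in% cases & pt_code %in% pt_codes,
                                .(report_id, pt_code)])
  m <- matrix(0L, nrow = length(cases), ncol = length(pt_codes),
              dimnames = list(cases, pt_codes))
  if (nrow(ev)) m[cbind(match(ev$report_id, cases), match(ev$pt_code, pt_codes))] <- 1L
  keep <- apply(m, 2L, function(x) length(unique(x)) > 1L)
  if (any(!keep))
    warning(sum(!keep), " zero-variance column(s) dropped: ",
            paste(pt_codes[!keep], collapse = ", "))
  m[, keep, drop = FALSE]
}

#' Estimate an Ising network by node-wise L1 logistic regression
#'
#' Each binary term is regressed on all others with an L1 penalty; the
#' penalty per node is chosen by the extended BIC
#' (`-2 loglik + df log n + 2 gamma df log(p - 1)`), and couplings are
#' symmetrised by the AND rule: an edge is kept only when each endpoint
#' selects the other, with weight the mean of the two logistic coefficients.
#' This is the standard sparse estimator for pairwise binary Markov
#' networks. Refuses matrices with fewer than 20 rows or 3 columns, where
#' the estimate is too unstable to interpret.
#'
#' @param m binary matrix (reports x terms).
#' @param ebic_gamma extended-BIC hyperparameter (0 = plain BIC; 0.25
#'   default favours mild sparsity).
#' @param and_rule use AND-rule symmetrisation (the default); `FALSE` keeps
#'   an edge when either direction selects it (OR rule), of which the AND
#'   network is always a subgraph.
#' @param min_rows,min_cols minimum matrix size.
#' @return an `event_network` list: `nodes`, `weights` (symmetric matrix),
#'   `method = "ising"`.
#' @export
fit_ising <- function(m, ebic_gamma = 0.25, and_rule = TRUE,
                      min_rows = 20L, min_cols = 3L) {
  m <- as.matrix(m)
  if (nrow(m) < min_rows || ncol(m) < min_cols)
    stop("matrix too small for a stable Ising fit (need >= ", min_rows,
         " rows and >= ", min_cols, " columns)")
  # drop perfectly collinear columns (later one goes)
  dup <- duplicated(t(m)) | duplicated(t(1L - m))
  if (any(dup)) {
    warning("collinear column(s) dropped: ",
            paste(colnames(m)[dup], collapse = ", "))
    m <- m[, !dup, drop = FALSE]
  }
  p <- ncol(m)
  n <- nrow(m)
  B <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(p)) {
    x <- m[, -j, drop = FALSE]
    y <- m[, j]
    if (length(unique(y)) < 2L) next
    fit <- glmnet::glmnet(x, y, family = "binomial", standardize = FALSE)
    dev <- (1 - fit$dev.ratio) * fit$nulldev   # -2 loglik up to a constant
    df <- fit$df
    ebic <- dev + df * log(n) + 2 * ebic_gamma * df * log(max(p - 1L, 1L))
    s <- which.min(ebic)
    beta <- as.numeric(fit$beta[, s])
    B[j, -j] <- beta
  }
  W <- if (and_rule) {
    keep <- (B != 0) & (t(B) != 0)
    (B + t(B)) / 2 * keep
  } else {
    keep <- (B != 0) | (t(B) != 0)
    # where only one direction is selected, use that coefficient
    (B + t(B)) / ifelse((B != 0) + (t(B) != 0) == 2, 2, 1) * keep
  }
  diag(W) <- 0
  structure(list(nodes = colnames(m), weights = W, method = "ising",
                 ebic_gamma = ebic_gamma, n = n), class = "event_network")
}

#' Positive pointwise mutual information network
#'
#' For terms a, b with row-wise relative frequencies `p(a)`, `p(b)` and
#' smoothed joint `p(a,b) = (n_ab + 0.5)/n`, the pointwise mutual
#' information is `log2(p(a,b) / (p(a) p(b)))`; the network weight is its
#' positive part, so weights are symmetric and non-negative with an empty
#' diagonal. The +0.5 joint smoothing keeps never-co-occurring pairs finite
#' (they clip to 0 anyway).
#'
#' @param m binary matrix (reports x terms), at least two columns.
#' @return an `event_network` with `method = "ppmi"`.
#' @export
compute_ppmi <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 2L)
  n <- nrow(m)
  pj <- colMeans(m)
  joint <- (crossprod(m) + 0.5) / n
  pmi <- log2(joint / outer(pj, pj))
  W <- pmax(pmi, 0)
  diag(W) <- 0
  stopifnot(isTRUE(all.equal(W, t(W))), all(W >= 0))
  structure(list(nodes = colnames(m), weights = W, method = "ppmi", n = n),
            class = "event_network")
}

#' @export
print.event_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("%s network: %d nodes, %d edges (n = %d reports)\n",
              x$method, length(x$nodes), ne, x$n))
  invisible(x)
}

#' Edge list of an event network
#'
#' @param net an `event_network`.
#' @return data.table with `pt_a`, `pt_b`, `weight`, `method`.
#' @export
network_edges <- function(net) {
  W <- net$weights
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.table(pt_a = rownames(W)[idx[, 1]], pt_b = colnames(W)[idx[, 2]],
             weight = W[idx], method = net$method)[order(-abs(weight))]
}

#' Community detection on an event network
#'
#' Walktrap community detection on the positive-weight subgraph (negative
#' Ising couplings do not contribute to community structure). Nodes without
#' any positive edge become singleton communities, with a warning when the
#' whole network is edgeless.
#'
#' @param net an `event_network`.
#' @param steps walktrap random-walk length.
#' @return named integer vector: community id per node.
#' @export
detect_communities <- function(net, steps = 4L) {
  W <- pmax(net$weights, 0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) {
    warning("edgeless network: every node is its own community")
    return(setNames(seq_along(net$nodes), net$nodes))
  }
  wt <- igraph::cluster_walktrap(g, steps = steps)
  setNames(igraph::membership(wt), net$nodes)
}

#' Compare two community partitions
#'
#' Adjusted Rand index between partitions of the same node set (1 =
#' identical, about 0 for unrelated labelings), plus the Jaccard overlap of
#' the two networks' edge sets when both networks are supplied - the two
#' estimation methods can agree on communities while disagreeing on edges,
#' and vice versa.
#'
#' @param p1,p2 named partition vectors over the same nodes.
#' @param net1,net2 optional `event_network`s for the edge Jaccard.
#' @return list with `ari` and (if networks given) `edge_jaccard`.
#' @export
compare_partitions <- function(p1, p2, net1 = NULL, net2 = NULL) {
  if (!setequal(names(p1), names(p2)))
    stop("partitions are over different node sets")
  p2 <- p2[names(p1)]
  out <- list(ari = adjusted_rand_index(p1, p2))
  if (!is.null(net1) && !is.null(net2)) {
    e1 <- .edge_keys(net1)
    e2 <- .edge_keys(net2)
    u <- length(union(e1, e2))
    out$edge_jaccard <- if (u == 0L) NA_real_ else length(intersect(e1, e2)) / u
  }
  out
}

.edge_keys <- function(net) {
  ed <- network_edges(net)
  if (nrow(ed) == 0L) return(character(0))
  paste(pmin(ed$pt_a, ed$pt_b), pmax(ed$pt_a, ed$pt_b), sep = "|")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same items:
#' `(sum_ij C(n_ij,2) - exp) / (max - exp)` over the contingency table of
#' the two partitions, where `exp` is the value expected under random
#' labelings with the same margins. 1 for identical partitions, about 0
#' for independent ones; can be negative.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(1)  # both partitions trivial and identical in structure
  (sij - exp_) / (max_ - exp_)
}

#' Draw samples from a small Ising model exactly
#'
#' Enumerates all 2^p states of a pairwise binary Markov network
#' `P(x) proportional to exp(h'x + x'Jx/2)` (x in {0,1}^p, J symmetric,
#' zero diagonal) and samples rows from the exact distribution. Intended
#' for validating network estimation on planted models; p is limited to 20.
#'
#' @param n number of rows.
#' @param J symmetric coupling matrix (upper triangle used).
#' @param h threshold vector.
#' @return binary matrix n x p.
#' @export
sample_ising <- function(n, J, h = rep(0, ncol(J))) {
  p <- ncol(J)
  stopifnot(p <= 20L, nrow(J) == p, length(h) == p,
            isTRUE(all.equal(J, t(J))))
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(states) <- colnames(J)
  loglik <- states %*% h + rowSums((states %*% J) * states) / 2
  pr <- exp(loglik - max(loglik))
  idx <- sample.int(nrow(states), n, replace = TRUE, prob = pr)
  states[idx, , drop = FALSE]
}
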