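# Exact solvers for the ambiguous-pixel labeling problem.
#
# Three interchangeable backends return a globally optimal labeling:
#   * solve_maxflow  - min-cut/max-flow on the standard s-t graph
#                      construction (default; the pairwise term is
#                      submodular for lambda >= 0, so min-cut is exact);
#   * solve_ilp      - the linearized 0-1 program, solved by HiGHS;
#   * solve_bruteforce - exhaustive enumeration (oracle, |A| <= 20).
# All backends share one objective bookkeeping (objective_components), so
# reported objective values are directly comparable.

new_labeling <- function(prob, labels, solver_name, status = "optimal") {
  comps <- objective_components(prob, labels)
  structure(
    list(
      labels = as.integer(labels),
      objective_value = comps$objective,
      o_idf = comps$o_idf, o_scf = comps$o_scf,
      solver_name = solver_name, status = status,
      n_variables = prob$n, n_edges = nrow(prob$edges),
      rows = prob$rows, cols = prob$cols, p = prob$p,
      lambda = prob$lambda, theta = prob$theta
    ),
    class = "maskrec_labeling"
  )
}

#' @export
print.maskrec_labeling <- function(x, ...) {
  cat(sprintf(
    "<maskrec_labeling> %d variable(s) via %s (%s): objective %.6f (O_idf %.6f, O_scf %.6f)\n",
    x$n_variables, x$solver_name, x$status,
    x$objective_value, x$o_idf, x$o_scf
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved labeling
#'
#' One row per ambiguous pixel: position, foreground probability and
#' assigned label.
#'
#' @param x a `maskrec_labeling`.
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `p`, `label`.
#' @method tidy maskrec_labeling
#' @export
tidy.maskrec_labeling <- function(x, ...) {
  tibble(row = x$rows, col = x$cols, p = x$p, label = x$labels)
}

#' One-row summary of a solved labeling
#'
#' @param x a `maskrec_labeling`.
#' @param ... unused.
#' @return a one-row tibble with the objective components and solver
#'   metadata.
#' @method glance maskrec_labeling
#' @export
glance.maskrec_labeling <- function(x, ...) {
  tibble(
    objective_value = x$objective_value, o_idf = x$o_idf, o_scf = x$o_scf,
    solver_name = x$solver_name, status = x$status,
    n_variables = x$n_variables, n_edges = x$n_edges,
    lambda = x$lambda, theta = x$theta
  )
}

# Optimality-preserving background-preferring sweep: flip any variable to
# 0 whose flip leaves the objective unchanged (exact ties only). Gives
# deterministic output at ties, in particular P = 0.5 pixels under
# lambda = 0 resolve to background.
canonicalize_labels <- function(prob, labels, tol = 1e-12) {
  n <- prob$n
  if (n == 0L) return(labels)
  adj_u <- split(seq_len(nrow(prob$edges)), prob$edges$u)
  adj_v <- split(seq_len(nrow(prob$edges)), prob$edges$v)
  fold_by_var <- split(seq_len(nrow(prob$folded)), prob$folded$var)
  lam <- prob$lambda

  for (pass in 1:5) {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (labels[i] != 1L) next
      delta <- prob$gain0[i] - prob$gain1[i]
      eids <- c(adj_u[[as.character(i)]], adj_v[[as.character(i)]])
      for (e in eids) {
        other <- if (prob$edges$u[e] == i) prob$edges$v[e] else prob$edges$u[e]
        delta <- delta - lam * prob$edges$s[e] *
          ((0L != labels[other]) - (1L != labels[other]))
      }
      for (fid in fold_by_var[[as.character(i)]]) {
        fl <- prob$folded$fixed_label[fid]
        delta <- delta - lam * prob$folded$s[fid] * ((0 != fl) - (1 != fl))
      }
      if (delta >= -tol) {
        labels[i] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

#' Solve the labeling problem by exhaustive enumeration
#'
#' Enumerates all `2^n` labelings of the ambiguous pixels and returns an
#' objective maximizer. Ties are broken by treating the labeling as a
#' binary number in raster order and taking the smallest, which prefers
#' background. Serves as the independent oracle for the other solvers;
#' limited to 20 variables.
#'
#' @param prob a `pixel_labeling_problem` with at most 20 variables.
#' @return a `maskrec_labeling`.
#' @export
solve_bruteforce <- function(prob) {
  n <- prob$n
  if (n > 20L) {
    abort("Brute force is limited to 20 ambiguous pixels; use solve_maxflow() or solve_ilp().")
  }
  if (n == 0L) return(new_labeling(prob, integer(0), "bruteforce"))

  total <- 2^n
  best_obj <- -Inf
  best <- NULL
  pow <- 2^((n - 1L):0)  # first pixel is the most significant bit
  chunk <- 2^14
  eu <- prob$edges$u; ev <- prob$edges$v; es <- prob$edges$s
  fv <- prob$folded$var; fs <- prob$folded$s; fl <- prob$folded$fixed_label
  lam <- prob$lambda
  k0 <- 0
  while (k0 < total) {
    ks <- k0:min(k0 + chunk - 1, total - 1)
    L <- outer(ks, pow, function(k, p) (k %/% p) %% 2)
    obj <- L %*% prob$gain1 + (1 - L) %*% prob$gain0
    if (length(eu)) {
      obj <- obj - lam * (abs(L[, eu, drop = FALSE] - L[, ev, drop = FALSE]) %*% es)
    }
    if (length(fv)) {
      diff <- sweep(L[, fv, drop = FALSE], 2, fl, function(a, b) (a != b) + 0)
      obj <- obj - lam * (diff %*% fs)
    }
    j <- which.max(obj)
    if (obj[j] > best_obj) {
      best_obj <- obj[j]
      best <- as.integer(L[j, ])
    }
    k0 <- k0 + chunk
  }
  new_labeling(prob, best, "bruteforce")
}

#' Solve the labeling problem exactly
#'
#' `solve_maxflow()` converts the maximization of the labeling objective
#' into a minimum s-t cut: unary gains become terminal capacities and the
#' pairwise weights `lambda * S` become edge capacities. For
#' `lambda >= 0` the pairwise term is submodular and the min-cut labeling
#' is a global optimum, with objective equal to [solve_ilp()]'s and
#' [solve_bruteforce()]'s.
#'
#' @param prob a `pixel_labeling_problem`.
#' @return a `maskrec_labeling`.
#' @export
solve_maxflow <- function(prob) {
  n <- prob$n
  if (n == 0L) return(new_labeling(prob, integer(0), "maxflow"))

  lam <- prob$lambda
  eff_gain1 <- prob$gain1
  eff_gain0 <- prob$gain0
  if (nrow(prob$folded) > 0L) {
    pen1 <- tapply(prob$folded$s * (prob$folded$fixed_label == 0), prob$folded$var, sum)
    pen0 <- tapply(prob$folded$s * (prob$folded$fixed_label == 1), prob$folded$var, sum)
    ids <- as.integer(names(pen1))
    eff_gain1[ids] <- eff_gain1[ids] - lam * as.numeric(pen1)
    eff_gain0[ids] <- eff_gain0[ids] - lam * as.numeric(pen0)
  }

  # label 1 = source side; cutting s->i pays the cost of label 0 and
  # cutting i->t pays the cost of label 1 (shifted to be non-negative)
  cost1 <- -eff_gain1
  cost0 <- -eff_gain0
  shift <- pmin(cost0, cost1)
  cap_source <- cost0 - shift
  cap_sink <- cost1 - shift

  src <- n + 1L; snk <- n + 2L
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  pos_s <- which(cap_source > 0)
  if (length(pos_s)) {
    from <- c(from, rep(src, length(pos_s))); to <- c(to, pos_s)
    cap <- c(cap, cap_source[pos_s])
  }
  pos_t <- which(cap_sink > 0)
  if (length(pos_t)) {
    from <- c(from, pos_t); to <- c(to, rep(snk, length(pos_t)))
    cap <- c(cap, cap_sink[pos_t])
  }
  if (nrow(prob$edges) > 0L && lam > 0) {
    w <- lam * prob$edges$s
    from <- c(from, prob$edges$u, prob$edges$v)
    to <- c(to, prob$edges$v, prob$edges$u)
    cap <- c(cap, w, w)
  }

  g <- igraph::make_empty_graph(n = n + 2L, directed = TRUE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$capacity <- cap
  }
  fl <- igraph::max_flow(g, source = src, target = snk,
                         capacity = igraph::E(g)$capacity)
  part1 <- as.integer(fl$partition1)
  if (!(src %in% part1)) part1 <- as.integer(fl$partition2)
  labels <- integer(n)
  labels[part1[part1 <= n]] <- 1L
  labels <- canonicalize_labels(prob, labels)
  new_labeling(prob, labels, "maxflow")
}

#' Solve the labeling problem as a 0-1 linear program
#'
#' Linearizes the absolute-value edge constraints
#' `e = |x_u - x_v|` as `e >= x_u - x_v` and `e >= x_v - x_u`
#' (maximization drives each `e` down to the true absolute value wherever
#' its coefficient `-lambda * S` is negative; when `lambda * S = 0` the
#' value of `e` is immaterial to the objective) and solves the resulting
#' 0-1 program with the HiGHS branch-and-bound solver, invoked through the
#' bundled Python helper. The optimum equals [solve_bruteforce()]'s.
#'
#' @param prob a `pixel_labeling_problem`.
#' @return a `maskrec_labeling`.
#' @export
solve_ilp <- function(prob) {
  solve_ilp_batch(list(prob))[[1L]]
}

#' @describeIn solve_ilp solve several problems in one solver invocation;
#'   returns a list of `maskrec_labeling` objects.
#' @param probs list of `pixel_labeling_problem` objects.
#' @export
solve_ilp_batch <- function(probs) {
  nonempty <- which(vapply(probs, function(p) p$n > 0L, logical(1)))
  results <- vector("list", length(probs))
  for (i in setdiff(seq_along(probs), nonempty)) {
    results[[i]] <- new_labeling(probs[[i]], integer(0), "ilp")
  }
  if (length(nonempty) == 0L) return(results)

  if (Sys.which("python") == "") {
    abort("No `python` with scipy found for the ILP backend; use solver = 'maxflow' or 'bruteforce'.")
  }
  payload <- lapply(probs[nonempty], function(p) {
    list(
      n = p$n,
      obj_x = I(p$gain1 - p$gain0),
      obj_e = I(if (nrow(p$edges)) -p$lambda * p$edges$s else numeric(0)),
      edge_u = I(p$edges$u), edge_v = I(p$edges$v),
      fold_var = I(p$folded$var),
      fold_pen1 = I(p$lambda * p$folded$s * (p$folded$fixed_label == 0)),
      fold_pen0 = I(p$lambda * p$folded$s * (p$folded$fixed_label == 1))
    )
  })
  script <- system.file("python", "solve_milp.py", package = "maskrec")
  if (script == "") abort("Bundled MILP helper script not found.")
  json_in <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2("python", shQuote(script), input = json_in, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  parsed <- tryCatch(jsonlite::fromJSON(paste(out, collapse = ""),
                                        simplifyVector = FALSE),
                     error = function(e) NULL)
  if ((!is.null(status) && status != 0) || is.null(parsed)) {
    abort(paste0(
      "ILP backend failed (python + scipy required); use solver = 'maxflow' or 'bruteforce'.\n",
      paste(utils::head(out, 5), collapse = "\n")
    ))
  }
  for (k in seq_along(nonempty)) {
    i <- nonempty[k]
    res <- parsed[[k]]
    if (!identical(res$status, "optimal")) {
      abort(sprintf("ILP solve reported '%s'; this labeling problem is feasible by construction, so this is an internal error.",
                    res$status))
    }
    labels <- canonicalize_labels(probs[[i]], as.integer(unlist(res$x)))
    results[[i]] <- new_labeling(probs[[i]], labels, "ilp")
  }
  results
}
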