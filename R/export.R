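#' Export / import a solved grid policy
#'
#' Writes the value and action tables as CSV (one row per grid point and
#' fixation: `grid_index`, `p_1..p_k`, `fixation`, `action_code`, `value`)
#' plus a JSON sidecar of solver metadata. Numeric values are serialized
#' with 17 significant digits, so the round trip is bit-exact.
#'
#' @param policy A solved grid policy.
#' @param csv_path CSV output path.
#' @param json_path JSON sidecar path (default: `csv_path` with `.json`).
#' @return `read_policy()` returns a `grid_policy` object reconstructed from
#'   the two files (usable for prediction and simulation).
#' @export
write_policy <- function(policy, csv_path,
                         json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(policy, "grid_policy"))
  g <- policy$grid; k <- g$k; F_ <- ncol(policy$action)
  df <- data.frame(
    grid_index = rep(seq_len(g$npoints), F_),
    fixation = rep(seq_len(F_), each = g$npoints))
  for (i in seq_len(k))
    df[[paste0("p_", i)]] <- sprintf("%.17g", g$points[df$grid_index, i])
  df$action_code <- as.vector(policy$action)
  df$value <- sprintf("%.17g", as.vector(policy$V))
  df <- df[, c("grid_index", paste0("p_", seq_len(k)), "fixation",
               "action_code", "value")]
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(family = policy$family, k = k, grid_n = g$n,
               n_fix = F_, declare_rule = policy$declare_rule,
               kind = policy$model$kind,
               tol = policy$tol, iterations = policy$iterations,
               stop_threshold = policy$stop_threshold,
               c = policy$costs$c, cs = policy$costs$cs,
               beta = policy$model$beta, betas = policy$model$betas,
               sweeps = policy$sweeps)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_policy
#' @param csv_path,json_path Paths written by `write_policy()`.
#' @export
read_policy <- function(csv_path,
                        json_path = sub("\\.csv$", ".json", csv_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  grid <- belief_grid(meta$k, meta$grid_n)
  model <- if (identical(meta$kind, "peripheral")) peripheral_model(meta$betas)
           else observation_model(meta$k, meta$beta)
  costs <- if (!is.null(meta$c)) cost_params(meta$c, meta$cs) else NULL
  npts <- grid$npoints
  ord <- order(df$fixation, df$grid_index)
  df <- df[ord, , drop = FALSE]
  action <- matrix(as.integer(df$action_code), npts, meta$n_fix)
  V <- matrix(as.numeric(df$value), npts, meta$n_fix)
  structure(
    list(V = V, action = action, model = model, costs = costs, grid = grid,
         declare_rule = meta$declare_rule, tol = meta$tol,
         iterations = meta$iterations, stop_threshold = meta$stop_threshold,
         family = meta$family, meta = meta),
    class = c(paste0(meta$family, "_policy"), "grid_policy", "sensing_policy"))
}
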