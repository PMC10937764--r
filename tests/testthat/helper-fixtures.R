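# Random decision trees with literal numeric probabilities, used to pit the
# rollback recursion against the path-enumeration oracle.
random_tree <- function(depth = 3, max_branch = 4, p_terminal = 0.3) {
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < p_terminal) {
      return(terminal_node(
        paste0("leaf_", sample.int(1e6, 1)),
        cost = round(stats::runif(1, 0, 1000), 2),
        effect = round(stats::runif(1, 0, 10), 2)
      ))
    }
    k <- sample(2:max_branch, 1)
    w <- stats::rgamma(k, 1) + 0.05
    p_chr <- sprintf("%.17g", w / sum(w))
    # make parsed probabilities sum to exactly 1
    p_num <- as.numeric(p_chr)
    p_chr[k] <- sprintf("%.17g", 1 - sum(p_num[-k]))
    branches <- lapply(seq_len(k), function(i) branch(p_chr[i], build(d - 1)))
    do.call(chance_node, c(
      list(paste0("chance_d", d, "_", sample.int(1e6, 1))),
      branches,
      list(cost = round(stats::runif(1, 0, 500), 2))
    ))
  }
  strategy_tree("random", build(depth))
}

empty_params <- function() {
  as_parameter_set(tibble::tibble(
    name = character(0), role = character(0), value = numeric(0),
    free = logical(0), lower = numeric(0), upper = numeric(0)
  ))
}

# two-parameter toy model: P(hit) = p -> cost c_hit, else fixed 200
toy_two_param <- function() {
  list(
    tree = strategy_tree("toy", chance_node(
      "event",
      branch("p_hit", terminal_node("hit", cost = "c_hit")),
      branch("1 - p_hit", terminal_node("miss", cost = 200))
    ), scalar_effect = 1),
    params = parameter_set(
      parameter("p_hit", "probability", 0.3),
      parameter("c_hit", "unit_cost", 500)
    )
  )
}
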