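# Shared fixtures built in code.

# Simulate n_blocks BLANK blocks for one direction and return the trial table.
sim_blank_trials <- function(params, seed, n_blocks = 17,
                             direction = "rightward") {
  do.call(rbind, lapply(seq_len(n_blocks), function(b)
    simulate_session(task_config("BLANK", direction),
                     params, seed = seed * 1000L + b)))
}

# Noiseless deterministic observer whose indifference point is mu:
# reports forward iff displacement > mu (at mu: forward, matching the
# tie-forward rule of the decision stage).
ideal_reports <- function(levels, mu) {
  ifelse(levels >= mu, "forward", "backward")
}

# Bernoulli draws from a known psychometric function, for recovery tests.
draw_psychometric <- function(levels, pss, jnd, seed, lapse = 0) {
  set.seed(seed)
  p <- lapse / 2 + (1 - lapse) * pnorm((levels - pss) / jnd)
  ifelse(runif(length(levels)) < p, "forward", "backward")
}

# Standard test lattice: the BLANK design levels in a +/-5 degree window.
blank_levels <- function(n_per_level = 20) {
  lev <- staircase_lattice(c(-3.5, 0, 3.5), 1.5, window = 5)$levels
  rep(lev, each = n_per_level)
}
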