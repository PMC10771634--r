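# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# assignments of the pooled values to the two groups (distinct values).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) # ties absent
  u_obs <- u_stat(a, b)
  combos <- combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

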