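# independent oracle: one-tailed exact MW p by direct enumeration over
# value assignments (not ranks), written separately from the implementation
brute_force_mw_p <- function(a, b, direction = "greater") {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_stat <- function(idx) {
    ga <- pooled[idx]; gb <- pooled[-idx]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  combos <- combn(n, n1)
  u_all <- apply(combos, 2, u_stat)
  if (direction == "greater") mean(u_all >= u_obs) else mean(u_all <= u_obs)
}
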