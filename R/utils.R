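# Shared internal helpers: deterministic rounding, seed fan-out, small checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder apportionment of `total` across non-negative weights.
# Ties in the fractional remainders are broken by position (stable, documented).
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

# Largest-remainder allocation clamped to per-bucket capacities; any excess is
# redistributed among unsaturated buckets by the same weights.
capped_allocation <- function(weights, caps, total) {
  stopifnot(length(weights) == length(caps))
  total <- min(total, sum(caps))
  alloc <- integer(length(weights))
  open <- rep(TRUE, length(weights))
  remaining <- total
  while (remaining > 0 && any(open & weights > 0)) {
    idx <- which(open)
    add <- largest_remainder(weights[idx], remaining)
    alloc[idx] <- alloc[idx] + add
    over <- alloc > caps
    if (any(over)) {
      remaining <- sum(alloc[over] - caps[over])
      alloc[over] <- caps[over]
      open <- open & !over
    } else {
      remaining <- 0L
    }
  }
  # degenerate case: weights all zero but room remains -> leave as is
  as.integer(alloc)
}

# Deterministic per-stage seed schedule fanned out from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
stage_seed <- function(master, index) {
  as.integer((as.double(master) * 10007 + index * 7919) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
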