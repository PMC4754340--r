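# shared internal helpers

# normal quantile used for 95% CIs throughout (matches standard meta-analysis
# software, not the rounded 1.96)
.Z95 <- 1.959964

# classed stop() so callers/tests can match on condition class
.tfStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tagfun_error", "error")))
}

# run `code` under set.seed(seed) without clobbering the caller's RNG stream
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .tfStop("`seed` must be a single non-missing number", "tagfun_param_error")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# accept "case"/"control", logical, factor or 0/1 coding; return integer 0/1
.statusToBinary <- function(status) {
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    bad <- !status %in% c("case", "control") & !is.na(status)
    if (any(bad)) {
      .tfStop("status must be 'case'/'control' (or 0/1)", "tagfun_param_error")
    }
    return(ifelse(is.na(status), NA_integer_, as.integer(status == "case")))
  }
  if (is.logical(status)) return(as.integer(status))
  if (is.numeric(status)) {
    if (any(!status %in% c(0, 1) & !is.na(status))) {
      .tfStop("numeric status must be 0/1", "tagfun_param_error")
    }
    return(as.integer(status))
  }
  .tfStop("unsupported status encoding", "tagfun_param_error")
}

.checkProb <- function(x, name, open = TRUE) {
  ok <- if (open) x > 0 & x < 1 else x >= 0 & x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !ok) {
    .tfStop(sprintf("`%s` must be a %s", name,
                    if (open) "frequency in (0, 1)" else "value in [0, 1]"),
            "tagfun_param_error")
  }
  invisible(x)
}

# Pearson chi-square for a 2x2 table of counts, closed form, vectorised over
# the four cell vectors; rows/columns with zero margins give statistic NA
.chisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  stat <- n * (a * d - b * c)^2 / denom
  stat[denom == 0] <- NA_real_
  stat
}
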