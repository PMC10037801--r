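# Internal numeric helpers shared across modules.

# trapezoidal rule; x must be sorted increasing
.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

.clamp <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

.leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
.leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# ELU with alpha = 1; derivative is exp(x) on the negative branch
.elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
.elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Xavier (Glorot) normal initialisation
.xavier <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, mean = 0, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# %.17g guarantees an exact double round trip, so write -> read -> write
# reproduces files byte for byte
.fmt_num <- function(x) sprintf("%.17g", x)

.is_binary <- function(x) all(x %in% c(0, 1))

.stop_if <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
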