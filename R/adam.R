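## Adam optimizer over a (possibly nested) named list of numeric arrays.
## Gradients are matched to parameters by name at each nesting level, so
## the C++ engine's gradient list and the parameter list stay in step.

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        gi <- if (!is.null(nm) && !is.null(names(g))) g[[nm[i]]] else g[[i]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      if (is.null(dim(p))) { g <- as.numeric(g) } else { dim(g) <- dim(p) }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
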