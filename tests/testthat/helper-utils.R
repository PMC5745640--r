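edge_strings <- function(model) {
  em <- model$dag$edges
  paste0(em[, 1L], "->", em[, 2L])
}

# Direct evaluation of the scenario-1 adjustment double-sum
# logit[ sum_{Z,T} P(Y=1|x,T) P(T|Z) P(Z) ] - independent of the
# joint-table machinery.
fig1a_double_sum_ace <- function(model) {
  pz <- model$root_prevalence[["Z"]]
  pT <- function(z) plogis(model$intercept[["T"]] +
                             model$edge_effect[["Z->T"]] * z)
  pY <- function(x, t) plogis(model$intercept[["Y"]] +
                                model$edge_effect[["X->Y"]] * x +
                                model$edge_effect[["T->Y"]] * t)
  std <- function(x) {
    tot <- 0
    for (z in 0:1) for (t in 0:1)
      tot <- tot + pY(x, t) * (if (t == 1) pT(z) else 1 - pT(z)) *
        (if (z == 1) pz else 1 - pz)
    tot
  }
  qlogis(std(1)) - qlogis(std(0))
}
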