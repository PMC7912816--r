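#' Candidate causal models for truffle fruitbody development
#'
#' The eight competing path models over harvest characters. For fruitbodies
#' growing singly the variables are harvesting date (\code{HD}), fruiting
#' depth class (\code{depth}), fresh weight (\code{weight}), shape index
#' (\code{shape}) and spore maturity (\code{maturity}). For fruitbody
#' clusters maturity is unavailable and the weight splits into the largest
#' fruitbody of the dig (\code{we_largest}) and the combined weight of the
#' remaining ones (\code{we_rest}).
#'
#' All single-fruitbody models share the edges \code{HD -> weight},
#' \code{HD -> maturity} and \code{weight -> shape}; model A adds nothing
#' (characters tied to one morphogenetic stage are untouched by earlier
#' stages), model B lets fruiting depth influence weight and maturity and
#' weight influence maturity, and model C additionally lets depth influence
#' shape. All cluster models share \code{HD -> we_largest},
#' \code{HD -> we_rest} and \code{we_largest -> shape}; B and C add depth
#' effects on the weights (C also on shape), D and E instead (respectively
#' additionally) let the weight of the remaining fruitbodies influence the
#' largest one and its shape.
#'
#' Families and transforms follow the analysis conventions: Poisson for
#' depth class and shape index, Gaussian for log-transformed weights and
#' for maturity, Gamma for the combined weight of the remaining
#' fruitbodies.
#'
#' @return A named list of \code{"causal_model"} objects:
#'   \code{single_A}, \code{single_B}, \code{single_C},
#'   \code{cluster_A} \dots \code{cluster_E}.
#' @examples
#' sapply(truffle_models(), function(m) 2 * length(basis_set(m)))
#' @export
truffle_models <- function() {
  single_v <- c("HD", "depth", "weight", "shape", "maturity")
  single_fam <- c(HD = "gaussian", depth = "poisson", weight = "gaussian",
                  shape = "poisson", maturity = "gaussian")
  single_trf <- c(weight = "log")
  sA <- list(c("HD", "weight"), c("HD", "maturity"), c("weight", "shape"))
  sB <- c(sA, list(c("depth", "weight"), c("depth", "maturity"),
                   c("weight", "maturity")))
  sC <- c(sB, list(c("depth", "shape")))

  cluster_v <- c("HD", "depth", "we_largest", "we_rest", "shape")
  cluster_fam <- c(HD = "gaussian", depth = "poisson",
                   we_largest = "gaussian", we_rest = "gamma",
                   shape = "poisson")
  cluster_trf <- c(we_largest = "log", we_rest = "log")
  cA <- list(c("HD", "we_largest"), c("HD", "we_rest"),
             c("we_largest", "shape"))
  cB <- c(cA, list(c("depth", "we_largest"), c("depth", "we_rest")))
  cC <- c(cB, list(c("depth", "shape")))
  cD <- c(cA, list(c("we_rest", "we_largest"), c("we_rest", "shape")))
  cE <- c(cB, list(c("we_rest", "we_largest"), c("we_rest", "shape")))

  mk_single <- function(name, edges)
    causal_model(name, single_v, edges, single_fam, single_trf)
  mk_cluster <- function(name, edges)
    causal_model(name, cluster_v, edges, cluster_fam, cluster_trf)

  list(single_A = mk_single("single_A", sA),
       single_B = mk_single("single_B", sB),
       single_C = mk_single("single_C", sC),
       cluster_A = mk_cluster("cluster_A", cA),
       cluster_B = mk_cluster("cluster_B", cB),
       cluster_C = mk_cluster("cluster_C", cC),
       cluster_D = mk_cluster("cluster_D", cD),
       cluster_E = mk_cluster("cluster_E", cE))
}
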