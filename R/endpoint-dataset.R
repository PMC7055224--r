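#' Assemble a labeled modeling dataset for a QSAR endpoint rule
#'
#' Joins hit calls to the descriptor matrix under one of the model-family
#' labeling rules:
#' \describe{
#'   \item{`luciferase`}{active in the luciferase-inhibition endpoint.}
#'   \item{`channel_any_condition`}{active in at least one culture condition
#'     of the given `channel` (the per-color models).}
#'   \item{`any_channel_all_conditions`}{active across all four culture
#'     conditions of at least one color channel (the general
#'     autofluorescence model's strong actives).}
#'   \item{`single_endpoint`}{active in the single endpoint `endpoint_id`
#'     (the per-channel-and-condition models).}
#' }
#'
#' @param hits Hit-call table from [call_hits()].
#' @param desc_matrix Descriptor matrix (rownames = chem ids).
#' @param rule Rule name (above).
#' @param channel,endpoint_id Rule parameters where applicable.
#' @param endpoints Endpoint metadata, default [interference_endpoints()].
#' @return List: `X` (descriptor rows for chemicals present in both inputs),
#'   `labels` (named logical), `rule` (provenance record).
#' @export
assemble_endpoint_dataset <- function(hits, desc_matrix, rule, channel = NULL,
                                      endpoint_id = NULL,
                                      endpoints = interference_endpoints()) {
  rule <- match.arg(rule, c("luciferase", "channel_any_condition",
                            "any_channel_all_conditions", "single_endpoint"))
  af <- endpoints[endpoints$technology == "autofluorescence", ]
  active_in <- function(eps) {
    sub <- hits[hits$endpoint_id %in% eps & hits$active, ]
    unique(sub$chem_id)
  }
  pos <- switch(rule,
    luciferase = active_in("luciferase"),
    channel_any_condition = {
      stopifnot(!is.null(channel))
      active_in(af$endpoint_id[af$channel == channel])
    },
    any_channel_all_conditions = {
      per_chan <- lapply(split(af$endpoint_id, af$channel), function(eps) {
        Reduce(intersect, lapply(eps, active_in))
      })
      unique(unlist(per_chan))
    },
    single_endpoint = {
      stopifnot(!is.null(endpoint_id))
      if (!endpoint_id %in% endpoints$endpoint_id) {
        stop("unknown endpoint id: ", endpoint_id)
      }
      active_in(endpoint_id)
    }
  )
  ids <- intersect(rownames(desc_matrix), unique(hits$chem_id))
  if (!length(ids)) stop("hit calls and descriptor matrix share no chemical ids")
  labels <- stats::setNames(ids %in% pos, ids)
  list(X = desc_matrix[ids, , drop = FALSE], labels = labels,
       rule = list(rule = rule, channel = channel, endpoint_id = endpoint_id,
                   n_positive = sum(labels), n_total = length(labels)))
}
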