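#' Default analyte panel
#'
#' The panel of analytes handled by the pipeline: 15 organochlorine
#' pesticides (OCPs) and 18 PCB congeners, split into non-dioxin-like
#' (ndl) and dioxin-like (mono-ortho and non-ortho) families. The family
#' determines the downstream path: OCPs feed the LADD/HQ screening,
#' dioxin-like PCBs feed the TEF-weighted TEQ, ndl-PCBs only appear in
#' summary tables.
#'
#' Detection limits default to 0.01 ng/g wet weight (the average
#' pesticide LOD of the underlying GC-MS method); quantification limits
#' are per-compound where reported, otherwise family defaults (0.01 ng/g
#' for pesticides, 0.065 ng/g — the midpoint of the reported 0.03–0.1
#' range — for PCB congeners). Both are overridable via
#' [read_reference_config()].
#'
#' @param config optional parsed reference config (see
#'   [read_reference_config()]) whose `lod`/`loq` sections override the
#'   defaults.
#' @return A data.frame with columns `analyte_id`, `family`
#'   (`"OCP"`, `"ndl-PCB"`, `"mono-ortho-PCB"`, `"non-ortho-PCB"`),
#'   `display_name`, `lod`, `loq` (ng/g wet weight).
#' @examples
#' panel <- default_panel()
#' table(panel$family)
#' @export
default_panel <- function(config = NULL) {
  ocp <- data.frame(
    analyte_id = c("aHCH", "bHCH", "gHCH", "dHCH", "aldrin", "dieldrin",
                   "pp_DDT", "pp_DDD", "pp_DDE", "endosulfan_a",
                   "endosulfan_b", "endosulfan_sulfate", "heptachlor",
                   "endrin_ketone", "methoxychlor"),
    family = "OCP",
    display_name = c("alpha-HCH", "beta-HCH", "gamma-HCH (lindane)",
                     "delta-HCH", "Aldrin", "Dieldrin", "p,p'-DDT",
                     "p,p'-DDD", "p,p'-DDE", "Endosulfan alpha",
                     "Endosulfan beta", "Endosulfan sulfate",
                     "Heptachlor", "Endrin ketone", "Methoxychlor"),
    stringsAsFactors = FALSE
  )
  pcb_ids <- c(ndl = "PCB28", ndl = "PCB52", ndl = "PCB101",
               ndl = "PCB138", ndl = "PCB153", ndl = "PCB180",
               mono = "PCB105", mono = "PCB114", mono = "PCB118",
               mono = "PCB123", mono = "PCB156", mono = "PCB157",
               mono = "PCB167", mono = "PCB189",
               non = "PCB77", non = "PCB81", non = "PCB126",
               non = "PCB169")
  pcb <- data.frame(
    analyte_id = unname(pcb_ids),
    family = c(ndl = "ndl-PCB", mono = "mono-ortho-PCB",
               non = "non-ortho-PCB")[names(pcb_ids)],
    display_name = sub("PCB", "PCB ", unname(pcb_ids)),
    stringsAsFactors = FALSE
  )
  panel <- rbind(ocp, pcb)
  rownames(panel) <- NULL

  lod_cfg <- config$lod %||% list()
  loq_cfg <- config$loq %||% list()
  is_ocp <- panel$family == "OCP"
  def_lod <- ifelse(is_ocp,
                    lod_cfg$default_ocp %||% 0.01,
                    lod_cfg$default_pcb %||% 0.01)
  def_loq <- ifelse(is_ocp,
                    loq_cfg$default_ocp %||% 0.01,
                    loq_cfg$default_pcb %||% 0.065)
  per_analyte <- function(cfg, defaults) {
    vapply(seq_len(nrow(panel)), function(i) {
      as.numeric(cfg[[panel$analyte_id[i]]] %||% defaults[i])
    }, numeric(1))
  }
  panel$lod <- per_analyte(lod_cfg, def_lod)
  panel$loq <- pmax(per_analyte(loq_cfg, def_loq), panel$lod)

  if (anyDuplicated(panel$analyte_id))
    stop_fr("analyte_id values must be unique in the panel")
  panel
}

#' @rdname default_panel
#' @param panel an analyte panel as returned by [default_panel()].
#' @return `dl_pcb_ids()`: character vector of the 12 dioxin-like
#'   congener ids (non-ortho + mono-ortho).
#' @export
dl_pcb_ids <- function(panel = default_panel()) {
  panel$analyte_id[panel$family %in% c("mono-ortho-PCB", "non-ortho-PCB")]
}

#' @rdname default_panel
#' @return `ocp_ids()`: character vector of pesticide analyte ids.
#' @export
ocp_ids <- function(panel = default_panel()) {
  panel$analyte_id[panel$family == "OCP"]
}

panel_lookup <- function(panel, analyte_id) {
  idx <- match(analyte_id, panel$analyte_id)
  if (anyNA(idx)) {
    missing <- unique(analyte_id[is.na(idx)])
    stop_fr("unknown analyte id(s): %s", paste(missing, collapse = ", "))
  }
  idx
}
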