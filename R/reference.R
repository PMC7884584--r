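#' Reference tables: TEFs, reference doses, intake and TWI constants
#'
#' All regulatory constants enter the pipeline as data, never as
#' literals in formulas: WHO 2005 toxic equivalency factors for the 12
#' dioxin-like PCB congeners, chronic oral reference doses (mg/kg/day)
#' for the screened pesticides, the two daily-consumption figures (the
#' HQ path uses 34.30 g/day; the TEQ/weekly-intake path uses
#' 34.19 g/day, i.e. 12.48 kg/yr), the adult body weight (70 kg), and
#' the former (14) and current (2) tolerable weekly intakes in
#' pg-TEQ/kg bw/week.
#'
#' `default_reference_tables()` loads the configuration shipped with
#' the package (`inst/extdata/reference_config.yaml`, which documents
#' the sources); `read_reference_config()` parses any YAML file with
#' the same sections (`tef`, `rfd`, `lod`, `loq`, `intake`, `twi`).
#'
#' @param path path to a YAML reference configuration.
#' @return A list of class `reference_tables` with elements `tef`
#'   (named numeric), `rfd` (named numeric), `adc_hq`, `adc_teq`, `bw`,
#'   `twi_old`, `twi_new`, and the raw `config` (for panel overrides).
#' @examples
#' ref <- default_reference_tables()
#' ref$tef[["PCB126"]]
#' @export
read_reference_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(c("tef", "rfd", "intake", "twi"), names(cfg))
  if (length(missing))
    stop_fr("reference config is missing section(s): %s",
            paste(missing, collapse = ", "))
  intake <- cfg$intake
  for (k in c("adc_hq", "adc_teq", "bw"))
    if (is.null(intake[[k]]))
      stop_fr("reference config intake section is missing '%s'", k)
  tef <- unlist(cfg$tef)
  rfd <- unlist(cfg$rfd)
  if (any(tef < 0 | tef > 1))
    stop_fr("all TEF values must lie in [0, 1]")
  if (any(rfd <= 0))
    stop_fr("all RfD values must be > 0")
  ref <- structure(list(
    tef = tef,
    rfd = rfd,
    adc_hq = assert_scalar_number(as.numeric(intake$adc_hq), "adc_hq",
                                  0, strict = TRUE),
    adc_teq = assert_scalar_number(as.numeric(intake$adc_teq), "adc_teq",
                                   0, strict = TRUE),
    bw = assert_scalar_number(as.numeric(intake$bw), "bw", 0, strict = TRUE),
    twi_old = as.numeric(cfg$twi$old),
    twi_new = as.numeric(cfg$twi$new),
    config = cfg
  ), class = "reference_tables")
  if (!(ref$twi_new < ref$twi_old))
    stop_fr("twi new (%g) must be below twi old (%g)", ref$twi_new, ref$twi_old)
  ref
}

#' @rdname read_reference_config
#' @export
default_reference_tables <- function() {
  read_reference_config(extdata_path("reference_config.yaml"))
}

#' @export
print.reference_tables <- function(x, ...) {
  cat("<reference_tables>\n")
  cat(sprintf("  %d TEFs | %d RfDs | ADC %.2f (HQ) / %.2f (TEQ) g/day | BW %g kg\n",
              length(x$tef), length(x$rfd), x$adc_hq, x$adc_teq, x$bw))
  cat(sprintf("  TWI %g (former) / %g (current) pg-TEQ/kg bw/week\n",
              x$twi_old, x$twi_new))
  invisible(x)
}
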