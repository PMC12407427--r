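# Shared loader for the analysis scripts: rebuilds the ensemble written by
# 01_simulate_ensemble.R (configs -> stacks deterministically, ERFs from CSV).

load_ensemble <- function(dir = "results/ensemble") {
  raw <- jsonlite::read_json(file.path(dir, "configs.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfgs <- lapply(raw, as_synthetic_city_config)
  stacks <- lapply(cfgs, make_city_stack)
  curves <- lapply(stacks, function(st)
    read_erf(file.path(dir, "erf", paste0(st$city_id, ".csv"))))
  names(curves) <- vapply(stacks, `[[`, character(1), "city_id")
  list(configs = cfgs, stacks = stacks, curves = curves)
}
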