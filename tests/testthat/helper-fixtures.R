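# Shared fixtures, built once per session and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_materials <- function() fixture("materials", load_material_table)

# coarse phase-1 benchmark model (d = 500 um)
fix_model_500 <- function() fixture("model500", function() {
  suppressWarnings(build_model(model_spec(d = 500e-6, phase = 1),
                               fix_materials()))
})

# small homogeneous cortical block
fix_block <- function() fixture("block", function() {
  homogeneous_block_model("Cortical", 4, 400e-6, fix_materials())
})

# physiological run on the coarse benchmark
fix_physio_500 <- function() fixture("physio500", function() {
  simulate_physio(fix_model_500(), physio_protocol(target = 100))
})

# ESWT run on the coarse benchmark
fix_eswt_500 <- function() fixture("eswt500", function() {
  simulate_eswt(fix_model_500(), eswt_protocol(EFD = 0.02))
})
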