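# Shared fixtures: small models built in code, plus an independent
# matrix-exponential solver used as a linear-ODE oracle.

neutral_test_compound <- function(fu = 1, log_p = 0) {
  compound("probe", mw = 200, log_p = log_p, ionization = "neutral",
           fu_plasma = fu, ka = 1, fa = 1)
}

unit_kp_set <- function(physiology) {
  tissues <- setdiff(physiology$organs$organ, c("arterial", "venous"))
  tibble::tibble(tissue = tissues, kp = 1, provenance = "test")
}

# A model that behaves as a single well-mixed volume: all drug mass sits in
# a large venous pool, every other compartment is negligible, Kp = 1, and
# blood flows are scaled up so hepatic extraction (CL relative to liver
# flow) is negligible and the whole body mixes fast.
near_one_compartment_model <- function(cl_L_h = 2, v_central = 10) {
  phys <- load_reference_physiology("adult_male")
  org <- phys$organs
  org$volume_L <- ifelse(org$organ == "venous", v_central, 1e-5)
  org$flow_L_h <- org$flow_L_h * 1000
  phys$organs <- org
  phys$cardiac_output <- phys$cardiac_output * 1000
  build_model(phys, neutral_test_compound(), unit_kp_set(phys),
              clearance_spec("linear", cl_L_h = cl_L_h, driving = "blood"))
}

# Standard small whole-body model used across engine tests.
standard_test_model <- function(cl_L_h = 4.38, driving = "blood",
                                tissue_kinetics = list(), kp_scale = 1) {
  phys <- load_reference_physiology("adult_male")
  cpd <- case_study_compound("ibuprofen")
  ps <- predict_partition_set(cpd, phys)
  ps$kp <- ps$kp * kp_scale
  build_model(phys, cpd, ps,
              clearance_spec("linear", cl_L_h = cl_L_h, driving = driving),
              tissue_kinetics = tissue_kinetics)
}

# Independent dense matrix exponential (scaling and squaring on the Taylor
# series); the oracle for linear flow-limited kinetics.
mat_exp <- function(M) {
  nrm <- max(rowSums(abs(M)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- M / 2^j
  E <- diag(nrow(M))
  term <- E
  for (k in 1:30) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(j)) E <- E %*% E
  E
}

# Build, directly from the model definition, the linear system matrix
# dA/dt = M A for a fully flow-limited model with linear blood-driven
# clearance and no oral depot. States: arterial, venous, lung, tissues.
flow_limited_matrix <- function(model) {
  phys <- model$physiology
  org <- phys$organs
  kp <- setNames(model$partition_set$kp, model$partition_set$tissue)
  tissues <- setdiff(org$organ, c("lung", "arterial", "venous"))
  states <- c("arterial", "venous", "lung", tissues)
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  vol <- setNames(org$volume_L, org$organ)
  flow <- setNames(org$flow_L_h, org$organ)
  co <- phys$cardiac_output
  M["lung", "venous"] <- co / vol["venous"]
  M["lung", "lung"] <- -co / vol["lung"] / kp["lung"]
  M["arterial", "lung"] <- co / vol["lung"] / kp["lung"]
  M["arterial", "arterial"] <- -co / vol["arterial"]
  q_liv <- flow["liver"] + flow["gut"]
  for (t in tissues) {
    out_rate <- flow[t] / vol[t] / kp[t]
    if (t == "gut") {
      M[t, "arterial"] <- flow[t] / vol["arterial"]
      M[t, t] <- -out_rate
      M["liver", t] <- out_rate * vol[t] / vol[t] # placeholder, fixed below
      M["liver", t] <- flow[t] / vol[t] / kp[t]
      next
    }
    if (t == "liver") {
      M[t, "arterial"] <- flow[t] / vol["arterial"]
      M[t, t] <- -(q_liv + model$clearance$cl_L_h) / vol[t] / kp[t]
      M["venous", t] <- q_liv / vol[t] / kp[t]
      next
    }
    M[t, "arterial"] <- flow[t] / vol["arterial"]
    M[t, t] <- -out_rate
    M["venous", t] <- out_rate
  }
  M["venous", "venous"] <- -co / vol["venous"]
  M
}
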