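#' Default structural adjacency of the CKD model
#'
#' The set of transitions the model structure permits. The default encodes:
#' incidence from the at-risk population into undiagnosed G1; stage-by-stage
#' progression within each diagnosis status (undiagnosed G4 progresses to
#' diagnosed G5, since stage 5 is always diagnosed); diagnosis transitions
#' undiagnosed k -> diagnosed k for stages 1-4; acute cardiovascular events
#' from diagnosed G3-G5; kidney replacement therapy from diagnosed G5
#' (dialysis or acute transplantation); transplantation from dialysis;
#' tunnel exits (acute -> post-acute); graft failure (post-acute
#' transplantation -> dialysis); death from every state; and self-loops in
#' every non-tunnel state. The graft-failure edge is a structural default
#' and can be removed by editing the returned matrix.
#'
#' @param space A state space from [ckd_states()].
#' @return A 16 x 16 logical matrix with dimnames; `TRUE` marks an allowed
#'   ordered transition.
#' @export
default_adjacency <- function(space = ckd_states()) {
  nm <- space$name
  A <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))

  edge <- function(from, to) A[from, to] <<- TRUE

  edge("No kidney disease", "Undiagnosed CKD G1")
  # stage progression, undiagnosed arm (G5 is always diagnosed)
  edge("Undiagnosed CKD G1", "Undiagnosed CKD G2")
  edge("Undiagnosed CKD G2", "Undiagnosed CKD G3")
  edge("Undiagnosed CKD G3", "Undiagnosed CKD G4")
  edge("Undiagnosed CKD G4", "Diagnosed CKD G5")
  # stage progression, diagnosed arm
  edge("Diagnosed CKD G1", "Diagnosed CKD G2")
  edge("Diagnosed CKD G2", "Diagnosed CKD G3")
  edge("Diagnosed CKD G3", "Diagnosed CKD G4")
  edge("Diagnosed CKD G4", "Diagnosed CKD G5")
  # diagnosis within stage
  edge("Undiagnosed CKD G1", "Diagnosed CKD G1")
  edge("Undiagnosed CKD G2", "Diagnosed CKD G2")
  edge("Undiagnosed CKD G3", "Diagnosed CKD G3")
  edge("Undiagnosed CKD G4", "Diagnosed CKD G4")
  # cardiovascular events
  edge("Diagnosed CKD G3", "CVD (acute)")
  edge("Diagnosed CKD G4", "CVD (acute)")
  edge("Diagnosed CKD G5", "CVD (acute)")
  # kidney replacement therapy
  edge("Diagnosed CKD G5", "Dialysis")
  edge("Diagnosed CKD G5", "Transplantation (acute)")
  edge("Dialysis", "Transplantation (acute)")
  edge("Transplantation (post-acute)", "Dialysis")  # graft failure
  # tunnel exits
  edge("Transplantation (acute)", "Transplantation (post-acute)")
  edge("CVD (acute)", "CVD (post-acute)")
  # death from everywhere; self-loops in non-tunnel states
  A[, "Death"] <- TRUE
  diag(A)[!space$tunnel] <- TRUE
  A["Death", ] <- FALSE
  A["Death", "Death"] <- TRUE
  A
}
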