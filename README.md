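# inquirydx

Reinforcement learning for staged diagnostic inquiry. `inquirydx`
implements an actor-critic agent that conducts an outpatient-style
consultation on a patient record: starting from demographics and the
chief concerns, it sequentially recommends symptom/history questions
(SMH), physical-examination checks (PE) and auxiliary-examination panels
(AE — one lab order yields all of the panel's recorded features), then
terminates with a probability distribution over diagnoses. It is aimed at
researchers studying sequential feature acquisition and clinical
decision-support prototyping.

## The model

The inquiry process is a Markov decision process with a forward-only
stage machine (SMH → PE → AE → diagnosis; earlier-stage actions are
masked to probability exactly 0). Three learned components interact:

- **Diagnostic model `D`** — a 5-layer MLP with softmax output, trained
  with cross-entropy on randomly masked observations so it handles any
  partial state the agent induces, and fine-tuned each training epoch on
  the observation sets the agent collected at termination.
- **Product-of-experts VAE** — the actor's backbone. Each observed
  feature contributes a Gaussian expert in a 64-d latent space via a
  shared encoder over `[value one-hot, feature embedding]`; experts and
  the spherical prior combine in closed form (precisions add, means are
  precision-weighted), and a decoder maps latent samples back to
  per-feature distributions, imputing what has not been asked yet.
- **Actor-critic with PPO** — the actor concatenates the decoded
  (imputed) features with `D(s_t)` and the budget ratio `n_t = t/N_T`
  and maps them through a 2-layer softmax head over legal actions; the
  critic scores `[s_t, D(s_t), n_t, z_t]` with a 5-layer MLP. PPO
  (clip 0.2, GAE λ = 0.95) updates only the actor head, the critic and
  the nested VAE decoder — encoder and embeddings stay frozen.

Rewards combine diagnostic-information gain
`Diff = |D_KL(y‖D(s_t)) − D_KL(y‖D(s_{t+1}))|` (zero for items absent
from the record), a bonus `α·I_phy` for physician-matching inquiries, and
stage-skip penalties `−m·M_stage` counting physician items the agent
jumped past (AE counted per panel). Termination pays a fixed reward for a
correct diagnosis and otherwise charges the remaining missed counts.
Presets: `"emergency"` (α = 0.2, m = 0.2, match reward 2, N_T = 21) and
`"pediatrics"` (α = 0.2, m = 0.3, match reward 3, N_T = 26).

Because real consultation corpora cannot ship with a package, a
synthetic-EHR world generator provides the test substrate: disease-
conditional feature emission with signature/background contrast set by a
separability parameter, compound two-disease diagnoses as separate label
classes, panels, stage-ordered physician sequences, and chief concerns
drawn from overlapping common symptoms.

## Worked example

A small end-to-end study on the default synthetic world (4 diseases plus
compound classes, 30 features, separability 0.9, inquiry budget 8):

```r
library(inquirydx)

res <- run_pipeline(seed = 1, verbose = TRUE)   # ~6-8 min on one core
print(res$reports$solo)
print(res$reports$random)
print(res$reports$collaboration)
res$reports$full_info
```

Output from this exact call (seed 1), in order solo / random /
collaboration:

```
EvaluationReport (300 episodes)
  macro AUROC 0.992 | macro F1 0.945 | accuracy 0.950 | general accuracy 0.973
  inquiries 8.00 (matching 3.74, physician 0.00) | recalled features 3.74
EvaluationReport (300 episodes)
  macro AUROC 0.779 | macro F1 0.387 | accuracy 0.443 | general accuracy 0.550
  inquiries 4.07 (matching 1.16, physician 0.00) | recalled features 1.59
EvaluationReport (300 episodes)
  macro AUROC 0.996 | macro F1 0.959 | accuracy 0.967 | general accuracy 0.993
  inquiries 7.22 (matching 7.22, physician 6.55) | recalled features 7.63
$diagnosis_model
[1] 0.9985543
$baseline
[1] 0.9993701
```

Reading it: with only 8 actions the trained agent reaches a macro AUROC
of 0.992 — within a point of the 0.999 a classifier sees with the
*complete* record — while a random-legal-action agent at the same budget
manages 0.78. In collaboration (agent recommends, a simulated physician
fills in on mismatches) most extracted features are recovered in fewer
inquiries than the physician originally used (7.2 vs 9.6) and accuracy
approaches the full-information reference.

The individual stages are available as exported functions:
`make_benchmark()` (world + records + 75/10/15 split), `train_vae()`,
`train_diagnosis_model()`, `train_physician_baseline()`, `train_agent()`,
`collect_rollouts()`, `simulate_collaboration()`, `evaluation_report()`,
`kendall_tau_normalized()`, `bootstrap_ci()`. A thin command-line wrapper
over the same functions is in `inst/cli/inquirydx.R`.

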