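---
title: "Staged diagnostic inquiry with a PoE-VAE actor-critic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged diagnostic inquiry with a PoE-VAE actor-critic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An outpatient consultation is a sequential information-gathering process.
The physician starts from demographics and the patient's chief concerns,
asks symptom and history questions (SMH), performs physical-examination
checks (PE), orders auxiliary examinations (AE — lab or imaging panels
where a single order yields many recorded features), and finally commits
to a diagnosis. `inquirydx` implements a reinforcement-learning agent for
this process: at each step it recommends the next inquiry item or
terminates with a probability distribution over diagnoses.

# The decision process

An episode is a Markov decision process over one patient record. The state
holds every observation so far — each feature's encoded value plus an
observed bit, and the demographic channel — together with the current
stage and the budget ratio $n_t = t/N_T$. Actions are: ask an SMH or PE
feature, ask an AE panel (asking any feature of an examination recommends
the whole examination, so panels are the action granularity), or
terminate. Stages are ordered SMH → PE → AE → termination and never move
backward: the probability of any earlier-stage action is forced to exactly
zero in the policy output. Answers come verbatim from the record's
extracted feature set; an item the record's physician never asked is
answered with an `asked_negative` sentinel. When $t$ reaches the budget
$N_T$ the episode is terminated forcibly and scored exactly as if the
agent had chosen to terminate.

## Rewards

Two channels shape the policy. For an inquiry of item $x$ taking the state
from $s_t$ to $s_{t+1}$:

$$R_\text{short} = \mathrm{Diff}(s_t, x, s_{t+1}) + \alpha\, I_\text{phy}(x) - m \cdot (\text{stage-skip penalty}),$$

where $\mathrm{Diff} = |D_{KL}(y\,\|\,D(s_t)) - D_{KL}(y\,\|\,D(s_{t+1}))|$
is the shift in KL divergence from the one-hot reference diagnosis $y$ to
the diagnostic model's output (for one-hot $y$ on class $c$ this is
$|\log D(s_{t+1})_c - \log D(s_t)_c|$, computed in nats), set to 0 when
$x$ is not among the extracted features; $I_\text{phy}$ indicates that the
physician also asked $x$; and the stage-skip penalty charges $m$ per
missed physician item when a transition jumps a stage ($M_\text{SMH}$ on
SMH→PE; $M_\text{SMH}+M_\text{PE}$ on SMH→AE; $M_\text{AE}$ on PE→AE as
printed in the reference description — a configuration switch
`pe_to_ae_penalty = "M_PE"` provides the pattern-consistent alternative,
since the printed case plausibly contains a typo; the default keeps the
printed form). $M_\text{AE}$ counts missed panels, not features: all
features within a laboratory test are one unit. On termination, a correct
diagnosis (argmax of $D$ against the reference label) earns the match
reward (2 in the emergency preset, 3 in pediatrics); a mismatch is charged
$m$ times the counts of missed physician items from the current stage
onward.

Constants follow the reference setting: $\alpha = 0.2$; $m = 0.2$
(emergency, $N_T = 21$) or $0.3$ (pediatrics, $N_T = 26$). The discount
$\gamma$ is never stated there; we default to the PPO-conventional 0.99
and expose it in the configuration. Natural logarithms are used throughout
(nats are the machine-learning convention, and the magnitudes of
$\alpha$ and $m$ suggest no rescaling).

# Networks

**Diagnostic model $D$** — a 5-layer MLP (4 hidden ReLU layers, softmax
output) trained with cross-entropy on state vectors. To handle the
arbitrary partial observations the agent induces, each training sample is
masked: every observed feature is kept with a probability drawn uniformly
from $(0.2, 1)$ per sample, and additionally a random subset of the
remaining features (per-sample rate uniform in $(0, 0.5)$) is set to the
`asked_negative` pattern — observed bit 1 with a zero value block. The
second component matters: a trained agent routinely asks items the record
never contained, so its terminal states are full of sentinel patterns; a
$D$ trained only on kept/dropped features misreads them badly enough to
push the trained agent below a random baseline. $D$ is additionally
fine-tuned between training epochs on the observation sets collected at
termination, with a best-snapshot guard so the buffer loss never
increases.

**PoE-VAE** — the actor's backbone. The decoder (4-layer MLP, parameters
$\Theta$) maps the 64-dimensional latent $z$ to per-feature distributions
(sigmoid for binary, softmax per level block otherwise). Each observed
feature $i$ contributes a Gaussian expert: a shared 4-layer encoder
(parameters $\Phi$) maps $c_i = [x_i, e_i]$ — the one-hot value block
padded to a common width plus a learned 64-dimensional embedding — to a
mean and a softplus-parameterized variance (floor $10^{-6}$). Partial
observations are combined in closed form: precisions add, means are
precision-weighted; the standard spherical prior participates as an expert
(standard PoE-VAE practice; a configuration flag can exclude it).
Pretraining maximizes the evidence lower bound over each record's
extracted features with a dropout schedule (per-sample keep probability
uniform in $(0.1, 1)$), with exact gradients through the
product-of-experts combination and the reparameterized sample (verified
against finite differences to $10^{-6}$). Two numerical safeguards keep
the latent informative at package-scale data: expert variances are
initialized sharp (variance-head bias $-2$, so initial $V \approx 0.13$),
and the KL term is annealed over the first 30% of epochs up to a weight
of 0.1 rather than 1 ($\beta$-style down-weighting). Without the latter
the optimizer collapses the posterior onto the prior — expert variances
grow into the hundreds and imputation degenerates to marginals — whereas
at weight 0.1 the learned conditionals match the generating rates. The
ELBO that is reported and tested is always the unweighted bound. $x_i$ inside $c_i$ is the one-hot value block —
the encoding of non-binary values is not specified by the reference
description, and one-hot is the natural choice consistent with the state
encoding.

**Actor and critic** — the actor feeds the observed features through the
nested VAE (encode → PoE → sample → decode), concatenates the decoded
(imputed) feature vector with $D(s_t)$ and $n_t$, and maps it through a
2-layer MLP head with masked softmax to the action space. The critic is a
5-layer MLP over $[s_t, D(s_t), n_t, z_t]$. During evaluation the latent
is the posterior mean and actions are greedy (ties to the lowest action
index); during training the latent is sampled and actions are drawn from
the policy.

**PPO** — clipped surrogate (clip 0.2), generalized advantage estimation
($\lambda = 0.95$), per-batch advantage normalization, entropy bonus
0.01, 4 update passes per batch, Adam. Only the VAE decoder, the actor
head and the critic receive gradients; the encoder and the embeddings are
asserted bitwise-frozen every epoch. These PPO constants are not given by
the reference description; they are the field's standard defaults and are
configuration-exposed.

# The synthetic world

The source EHR corpora are not distributable, so the package ships a
generator whose records have the statistical structure the method
assumes: disease-conditional feature emission, panels yielding several
features per inquiry, stage-ordered physician sequences, chief concerns as
a small subset of positive SMH features, and two-disease combinations as
separate label classes alongside the atomic diseases (the combination
scheme of the source data). Emission is a per-(label, feature) positivity
rate: $\theta_\text{sig} = 0.5 + 0.45 s$ for signature features against
$\theta_\text{bg} = 0.5 - 0.45 s$, with separability $s \in (0, 1]$, so
$s = 1$ yields the configured extremes 0.95 / 0.05. Compound labels emit
the element-wise maximum of their constituents' rates and carry half a
single class's prior mass.

The default world is deliberately *history-rich and syndromic*, for three
domain reasons that were fixed before any agent was trained on them:

1. Most diagnostic information in primary-care presentations comes from
   history-taking, so per-disease signature features sit mainly in the SMH
   stage (2 per disease), with one signature PE finding each and
   nonspecific routine lab panels.
2. Presenting complaints overlap heavily within a department: patients
   lead with common symptoms (a shared pool positive at rate 0.6 under
   every disease) as chief concerns whenever they have one, so the initial
   state is only weakly disease-identifying and inquiry has room to
   matter.
3. The stage machine makes skipped history irrecoverable, which is
   exactly what separates a considered inquiry policy from random probing.

The simulated physician asks signature and common items with probability
0.9 and anything else with probability 0.15, ordered within stage by
mutual information with the diagnosis (ties lexicographic); all recorded
values — including explicit negatives — enter the extracted set. Records
without a positive SMH feature are resampled (bounded retries).

What the generator does **not** emulate: free-text extraction noise,
inter-hospital recording variability beyond the single noise rate,
disease-dependent demographics, feature-feature correlations beyond the
shared disease cause, and realistic disease frequencies. Passing tests on
this substrate demonstrate that the machinery — rewards, stage machine,
PoE imputation, PPO optimization, evaluation statistics — behaves as
specified on data with the right structure; they do not certify clinical
performance.

# Evaluation

Diagnostic quality is summarized by one-vs-rest macro AUROC (classes
absent from the labels are skipped with a warning — macro averaging is
chosen for consistency with the macro-F1), macro F1, accuracy, and
*general accuracy*, which also credits a prediction that names one
constituent of a compound reference (or a compound containing the single
true disease); the precise rule is: constituent sets $P$ and $R$ score 1
iff $P = R$, or $P \cap R \neq \emptyset$ and $\min(|P|, |R|) = 1$.
Inquiry quality is summarized by counts of inquiries, physician-matching
inquiries, physician-conducted inquiries (collaboration only) and
recalled features (by stage, and positive-only — exhibited symptoms or
out-of-range labs). Uncertainty is quantified by percentile bootstrap
CIs (1000 resamples at the original size; percentile rather than BCa as
the simplest reading of a nonparametric bootstrap).

The collaboration protocol plays the agent's top recommendation at each
step; a recommendation matching the record is accepted, otherwise a
simulated physician picks an unasked extracted item uniformly from the
earliest stage at or after the current one (respecting stage legality),
and the episode ends on terminate or exhaustion. Inquiry-order
consistency with physicians uses the normalized Kendall tau distance on
the common items of the two sequences — the only well-defined restriction
when item sets differ; the match fraction is logged alongside.

The reference baseline ("simulated physician") is the best of several
standard classifier families — multinomial logistic regression and a
random forest — selected by validation macro AUROC on full extracted
observations.

# Numerical and design choices

- Feature index order is lexicographic by id, fixed at catalog load;
  every vector in the system uses it.
- Binary value blocks have length 1 (`[1]` = positive); tri-level blocks
  are one-hot over low/normal/high. The `asked_negative` sentinel is kept
  distinct in the environment's observation map but encodes as observed
  bit 1 with a zero value block — for binary features this coincides with
  an explicit negative. A dedicated one-hot level per feature was
  considered and rejected because it conflicts with the fixed block
  convention above.
- Demographics (age/100 and a gender one-hot with an explicit "unknown")
  are a separate channel appended to the state; the diagnostic model sees
  them because the agent's initial input includes them.
- Terminate does not consume a budget step ($N_T$ counts completed
  inquiries).
- Whether `Diff` requires the physician to have asked the feature, or
  merely that it appears in the record, is moot here: every extracted
  feature stems from a physician inquiry, so extracted-set membership is
  the criterion.
- Probabilities are clamped at $10^{-12}$ inside logs, with a warning
  when the clamp binds.
- Problem sizes used by the shipped studies: the recovery study trains on
  a 4-disease, 30-feature, separability-0.9 world with $N_T = 8$, 2000
  records (75/10/15 split), reduced widths (latent and embeddings 16,
  hidden 32), PPO for 300 epochs of 96 episodes — the return curve is
  still climbing at 200 epochs, and 300 sits on its plateau. Full-width
  (64-dimensional) networks are the package defaults for real use.

# Known limitations

- All networks are plain feed-forward MLPs on base-R matrix arithmetic;
  training at the scale of the source corpora (hundreds of thousands of
  records, hundreds of features) is out of scope.
- The retrospective-record evaluation inherits the source setting's
  asymmetry: an agent inquiry outside the extracted set yields no
  information, so solo-agent metrics are a conservative estimate.
- The simulated collaboration models a maximally passive physician;
  real collaboration would interleave judgment.
- Percentile bootstrap CIs undercover slightly for strongly skewed
  statistics.
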