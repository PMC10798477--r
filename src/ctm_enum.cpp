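#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Exhaustive Coding-Theorem enumeration of (n,2) Turing machines in the
// Wolfram (4n+2)-transition formalism: each (state, symbol) cell maps to
// either "halt writing 0/1" (no move) or (write, move L/R, next state).
// Machines start in state 1 on a blank tape; the output is the tape segment
// between the leftmost and rightmost head positions at which a transition
// was executed.  The output-frequency distribution is symmetrised over
// string reversal (mirror machines) and bit complementation (blank-1 runs),
// as in the published Coding Theorem Method constructions.
//
// Reduced enumeration: by the mirror/complement orbit structure and by
// relabelling of states >= 2, it suffices to run the two classes with
// delta(state 1, blank) = (write w, move R, goto 2) for w in {0,1}; every
// other halting first transition is either an orbit image (adds counts for
// the reversed / complemented / reverse-complemented output), a relabelling
// (global factor n-1), an immediate halt (output "0" or "1", counted
// analytically), or a machine that provably never halts (goto 1 runs off
// the tape forever).

// value encoding for a transition cell t in 0..4n+1:
//   t < 2          : halt, write t
//   u = t - 2      : write u&1, move ((u>>1)&1 ? +1 : -1), next (u>>2)+1

// [[Rcpp::export]]
List ctm_enum_cpp(int n_states, int max_steps, int max_len_keep = 14) {
  if (n_states < 2) stop("n_states must be >= 2");
  if (max_steps < 1) stop("max_steps must be >= 1");
  if (max_len_keep < 1 || max_len_keep > 24) stop("max_len_keep in 1..24");

  const int n = n_states;
  const int n_slots = 2 * n;            // (state, symbol) cells
  const int n_vals = 4 * n + 2;         // options per free cell
  const int n_free = n_slots - 1;       // cell (1, blank) is fixed

  // counts[len][code] for halting outputs with len <= max_len_keep
  std::vector< std::vector<double> > counts(max_len_keep + 1);
  for (int L = 1; L <= max_len_keep; ++L)
    counts[L].assign((size_t)1 << L, 0.0);
  std::vector<double> long_counts; long_counts.assign(1, 0.0); // len > keep
  double halted = 0.0, runs = 0.0;

  const int cap = max_steps;
  const int tape_len = 2 * cap + 8;
  const int center = cap + 4;
  std::vector<unsigned char> tape_v((size_t)tape_len, 0);
  unsigned char *tape = tape_v.data();

  int delta[64];                         // n <= 8 is plenty
  int digits[64];

  for (int w0 = 0; w0 <= 1; ++w0) {      // the two orbit representatives
    // fixed first transition: write w0, move right, goto state 2
    delta[0] = 2 + (w0) + 2 /*move R*/ + 4 /* (next-1)=1 -> u>>2==1 */ * 4;
    // recompute cleanly: u = write + 2*moveR + 4*(next-1)
    { int u = w0 + 2 * 1 + 4 * (2 - 1); delta[0] = u + 2; }
    for (int i = 0; i < n_free; ++i) { digits[i] = 0; delta[i + 1] = 2; }
    // delta[i+1] value for digit d is just d (0..n_vals-1)
    for (int i = 0; i < n_free; ++i) delta[i + 1] = 0;

    bool done = false;
    while (!done) {
      // ---- run machine ----
      runs += 1.0;
      int pos = center, state = 1, minp = center, maxp = center;
      bool halt = false;
      for (int step_i = 0; step_i < cap; ++step_i) {
        int c = tape[pos];
        int t = delta[2 * (state - 1) + c];
        if (t < 2) { tape[pos] = (unsigned char)t; halt = true; break; }
        int u = t - 2;
        tape[pos] = (unsigned char)(u & 1);
        pos += ((u >> 1) & 1) ? 1 : -1;
        state = (u >> 2) + 1;
        if (pos < minp) { if (pos < 2) break; minp = pos; }
        else if (pos > maxp) { if (pos > tape_len - 3) break; maxp = pos; }
      }
      if (halt) {
        halted += 1.0;
        int L = maxp - minp + 1;
        if (L <= max_len_keep) {
          size_t code = 0;
          for (int i = minp; i <= maxp; ++i) code = (code << 1) | tape[i];
          counts[L][code] += 1.0;
        } else {
          long_counts[0] += 1.0;
        }
      }
      // reset touched tape
      std::memset(tape + minp, 0, (size_t)(maxp - minp + 1));

      // ---- odometer over free cells ----
      int i = 0;
      for (; i < n_free; ++i) {
        if (++digits[i] < n_vals) { delta[i + 1] = digits[i]; break; }
        digits[i] = 0; delta[i + 1] = 0;
      }
      if (i == n_free) done = true;
      if (((long long)runs & 0xFFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  // assemble symmetrised counts: each enumerated halting machine stands for
  // the 4 orbit members producing s, rev(s), comp(s), revcomp(s), and for
  // n-1 relabellings of its first target state.
  List out_counts(max_len_keep);
  double relab = (double)(n - 1);
  for (int L = 1; L <= max_len_keep; ++L) {
    size_t m = (size_t)1 << L;
    NumericVector v((R_xlen_t)m);
    size_t mask = m - 1;
    for (size_t code = 0; code < m; ++code) {
      size_t rev = 0, x = code;
      for (int i = 0; i < L; ++i) { rev = (rev << 1) | (x & 1); x >>= 1; }
      size_t comp = (~code) & mask;
      size_t revcomp = (~rev) & mask;
      v[(R_xlen_t)code] = relab * (counts[L][code] + counts[L][rev] +
                                   counts[L][comp] + counts[L][revcomp]);
    }
    out_counts[L - 1] = v;
  }
  // immediate-halt classes: outputs "0" and "1", over both blanks
  double M = 1.0;
  for (int i = 0; i < n_free; ++i) M *= (double)n_vals;
  NumericVector v1 = out_counts[0];
  v1[0] += 2.0 * M;  // "0"
  v1[1] += 2.0 * M;  // "1"

  double total_halting = 4.0 * relab * halted + 4.0 * M;
  double long_total = 4.0 * relab * long_counts[0];

  return List::create(
    _["counts"] = out_counts,
    _["total_halting"] = total_halting,
    _["long_output_count"] = long_total,
    _["machines_run"] = runs,
    _["n_states"] = n,
    _["max_steps"] = max_steps);
}
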