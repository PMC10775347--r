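// Extended phase graph (EPG) engine for gradient-spoiled sequences with
// constant RF phase.  With phase-0 excitations and a real initial Mz the
// configuration states keep a fixed phase structure (F+_k = -i a_k,
// F-_k = +i b_k, Z_k real), so the whole recursion runs in real arithmetic.
// The readout convention is: a 90 degree tip of a fully recovered Mz with
// unit M0 yields |signal| = 1 (before TE decay).
//
// Atoms are processed in chunks with the dephasing order as the outer and
// the atom as the inner (vectorizable) index; relaxation factors are cached
// per distinct delay duration.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum EpgOp { OP_INV = 1, OP_SAT = 2, OP_DELAY = 3, OP_PULSE = 4, OP_SHIFT = 5 };

// [[Rcpp::export]]
NumericMatrix epg_simulate_cpp(IntegerVector op, NumericVector param,
                               NumericVector t1, NumericVector t2,
                               NumericVector b1, double te,
                               int n_orders, int n_groups, int keep_groups) {
  const int n_ev = op.size();
  const int n_atoms = t1.size();
  const int K = n_orders;
  const int CH = 64;  // atoms per chunk

  int n_read = 0;
  for (int e = 0; e < n_ev; ++e) if (op[e] == OP_PULSE) ++n_read;

  NumericMatrix out(n_atoms, n_read * keep_groups);

  // distinct delay durations -> index into relaxation cache
  std::unordered_map<double, int> delay_id;
  std::vector<double> delay_val;
  for (int e = 0; e < n_ev; ++e) {
    if (op[e] == OP_DELAY && delay_id.find(param[e]) == delay_id.end()) {
      delay_id[param[e]] = (int)delay_val.size();
      delay_val.push_back(param[e]);
    }
  }
  const int n_delay = (int)delay_val.size();

  std::vector<double> a((K + 1) * CH), b((K + 1) * CH), z((K + 1) * CH);
  std::vector<double> E1(n_delay * CH), E2(n_delay * CH), R0(n_delay * CH);
  std::vector<double> e2te(CH), sa(CH), ca(CH), c2a(CH), s2a(CH);

  for (int at0 = 0; at0 < n_atoms; at0 += CH) {
    const int nc = std::min(CH, n_atoms - at0);

    for (int j = 0; j < nc; ++j) {
      e2te[j] = std::exp(-te / t2[at0 + j]);
      for (int d = 0; d < n_delay; ++d) {
        E1[d * CH + j] = std::exp(-delay_val[d] / t1[at0 + j]);
        E2[d * CH + j] = std::exp(-delay_val[d] / t2[at0 + j]);
        R0[d * CH + j] = 1.0 - E1[d * CH + j];
      }
    }
    std::fill(a.begin(), a.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    std::fill(z.begin(), z.end(), 0.0);
    for (int j = 0; j < nc; ++j) z[j] = 1.0;

    for (int g = 0; g < n_groups; ++g) {
      const bool keep = (g >= n_groups - keep_groups);
      int ir = 0;
      for (int e = 0; e < n_ev; ++e) {
        switch (op[e]) {
        case OP_INV:
          for (int k = 0; k <= K; ++k) {
            double* zk = &z[k * CH];
            for (int j = 0; j < nc; ++j) zk[j] = -zk[j];
          }
          break;
        case OP_SAT:
          std::fill(a.begin(), a.end(), 0.0);
          std::fill(b.begin(), b.end(), 0.0);
          std::fill(z.begin(), z.end(), 0.0);
          break;
        case OP_DELAY: {
          const int d = delay_id[param[e]];
          const double* e1 = &E1[d * CH];
          const double* e2 = &E2[d * CH];
          const double* r0 = &R0[d * CH];
          for (int k = 0; k <= K; ++k) {
            double* ak = &a[k * CH];
            double* bk = &b[k * CH];
            double* zk = &z[k * CH];
            for (int j = 0; j < nc; ++j) {
              ak[j] *= e2[j]; bk[j] *= e2[j]; zk[j] *= e1[j];
            }
          }
          for (int j = 0; j < nc; ++j) z[j] += r0[j];
          break;
        }
        case OP_PULSE: {
          const double fa = param[e] * M_PI / 180.0;
          for (int j = 0; j < nc; ++j) {
            const double al = b1[at0 + j] * fa;
            sa[j] = std::sin(al); ca[j] = std::cos(al);
            c2a[j] = 0.5 * (1.0 + ca[j]);  // cos^2(al/2)
            s2a[j] = 1.0 - c2a[j];
          }
          for (int k = 0; k <= K; ++k) {
            double* ak = &a[k * CH];
            double* bk = &b[k * CH];
            double* zk = &z[k * CH];
            for (int j = 0; j < nc; ++j) {
              const double aj = ak[j], bj = bk[j], zj = zk[j];
              ak[j] = c2a[j] * aj - s2a[j] * bj + sa[j] * zj;
              bk[j] = -s2a[j] * aj + c2a[j] * bj + sa[j] * zj;
              zk[j] = -0.5 * sa[j] * (aj + bj) + ca[j] * zj;
            }
          }
          if (keep) {
            const int col = (g - (n_groups - keep_groups)) * n_read + ir;
            for (int j = 0; j < nc; ++j) out(at0 + j, col) = a[j] * e2te[j];
          }
          ++ir;
          break;
        }
        case OP_SHIFT: {
          // F-: shift down (b_k <- b_{k+1}); F+: shift up, a_0 <- old b_1
          for (int j = 0; j < nc; ++j) sa[j] = b[CH + j];  // old b_1
          for (int k = 0; k < K; ++k) {
            double* bk = &b[k * CH];
            const double* bk1 = &b[(k + 1) * CH];
            for (int j = 0; j < nc; ++j) bk[j] = bk1[j];
          }
          std::fill(&b[K * CH], &b[K * CH] + nc, 0.0);
          for (int k = K; k >= 1; --k) {
            double* ak = &a[k * CH];
            const double* ak1 = &a[(k - 1) * CH];
            for (int j = 0; j < nc; ++j) ak[j] = ak1[j];
          }
          for (int j = 0; j < nc; ++j) a[j] = sa[j];
          break;
        }
        default:
          stop("unknown EPG opcode");
        }
      }
    }
  }
  return out;
}
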