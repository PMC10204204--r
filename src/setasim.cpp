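// Core numerics: elastic chain forces, viscous particle-seta coupling,
// Morse adhesion, and the coupled time-stepper. All randomness goes through
// R's RNG so runs are reproducible from a single set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double COINCIDENT_TOL2 = 1e-24;

// Elastic forces for one chain as the exact negative gradient of
//   U = sum_bonds kpar/(8 dR^2) (l^2 - dR^2)^2
//     + sum_interior kperp/2 |r_j - (r_{j-1}+r_{j+1})/2|^2
// The transverse part therefore places the midpoint-restoring force on the
// interior node and half-reactions on its neighbours (momentum conserving).
static void chain_forces(const double* x, const double* y, const double* z,
                         int nseg, double dR,
                         const double* kpar, const double* kperp,
                         double* fx, double* fy, double* fz)
{
    const int nn = nseg + 1;
    std::fill(fx, fx + nn, 0.0);
    std::fill(fy, fy + nn, 0.0);
    std::fill(fz, fz + nn, 0.0);
    const double inv2 = 1.0 / (2.0 * dR * dR);
    const double dR2 = dR * dR;
    for (int i = 1; i < nn; ++i) {
        const double dx = x[i] - x[i - 1];
        const double dy = y[i] - y[i - 1];
        const double dz = z[i] - z[i - 1];
        const double l2 = dx * dx + dy * dy + dz * dz;
        if (l2 < COINCIDENT_TOL2)
            stop("coincident chain nodes %d and %d: bond direction undefined", i, i + 1);
        const double c = -kpar[i - 1] * inv2 * (l2 - dR2);
        fx[i] += c * dx; fx[i - 1] -= c * dx;
        fy[i] += c * dy; fy[i - 1] -= c * dy;
        fz[i] += c * dz; fz[i - 1] -= c * dz;
    }
    for (int j = 1; j < nn - 1; ++j) {
        const double k = kperp[j - 1]; // segment j has distal node j
        if (k == 0.0) continue;
        const double dx = x[j] - 0.5 * (x[j - 1] + x[j + 1]);
        const double dy = y[j] - 0.5 * (y[j - 1] + y[j + 1]);
        const double dz = z[j] - 0.5 * (z[j - 1] + z[j + 1]);
        fx[j] -= k * dx; fx[j - 1] += 0.5 * k * dx; fx[j + 1] += 0.5 * k * dx;
        fy[j] -= k * dy; fy[j - 1] += 0.5 * k * dy; fy[j + 1] += 0.5 * k * dy;
        fz[j] -= k * dz; fz[j - 1] += 0.5 * k * dz; fz[j + 1] += 0.5 * k * dz;
    }
}

// Dense-banded backward-Euler Newton step for the free nodes
// (index >= 2) of one chain: solves u - u0 - (dt/gamma) F(u) = 0.
// Returns false if Newton fails to converge.
static bool implicit_relax_step(double* x, double* y, double* z, int nseg,
                                double dR, const double* kpar,
                                const double* kperp, double dt, double gamma_s)
{
    const int nn = nseg + 1;
    const int nfree = nn - 2;
    if (nfree <= 0) return true;
    const int m = 3 * nfree;
    const int kb = 8; // coupling extends two nodes each way
    const int ld = 2 * kb + 1;
    const double hg = dt / gamma_s;
    std::vector<double> fx(nn), fy(nn), fz(nn);
    std::vector<double> u0(m), g(m), amat((size_t)ld * m);
    for (int j = 0; j < nfree; ++j) {
        u0[3 * j] = x[j + 2]; u0[3 * j + 1] = y[j + 2]; u0[3 * j + 2] = z[j + 2];
    }
    const double inv2 = 1.0 / (2.0 * dR * dR);
    const double dR2 = dR * dR;
    for (int iter = 0; iter < 40; ++iter) {
        chain_forces(x, y, z, nseg, dR, kpar, kperp,
                     fx.data(), fy.data(), fz.data());
        double gmax = 0.0;
        for (int j = 0; j < nfree; ++j) {
            g[3 * j]     = x[j + 2] - u0[3 * j]     - hg * fx[j + 2];
            g[3 * j + 1] = y[j + 2] - u0[3 * j + 1] - hg * fy[j + 2];
            g[3 * j + 2] = z[j + 2] - u0[3 * j + 2] - hg * fz[j + 2];
            gmax = std::max(gmax, std::fabs(g[3 * j]));
            gmax = std::max(gmax, std::fabs(g[3 * j + 1]));
            gmax = std::max(gmax, std::fabs(g[3 * j + 2]));
        }
        if (gmax < 1e-12 * dR) return true;
        // assemble J_G = I - hg * J_F on the free-node block (banded)
        std::fill(amat.begin(), amat.end(), 0.0);
        // helper to add val to block entry (node a, comp ca; node b, comp cb)
        auto add = [&](int na, int ca, int nb, int cb, double val) {
            if (na < 2 || nb < 2 || na >= nn || nb >= nn) return;
            const int i = 3 * (na - 2) + ca;
            const int j = 3 * (nb - 2) + cb;
            amat[(i - j + kb) + (size_t)ld * j] -= hg * val; // J_G -= hg*J_F
        };
        for (int i = 0; i < m; ++i) amat[kb + (size_t)ld * i] += 1.0;
        for (int i = 1; i < nn; ++i) { // longitudinal bonds
            const double d[3] = { x[i] - x[i - 1], y[i] - y[i - 1],
                                  z[i] - z[i - 1] };
            const double l2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
            const double c = kpar[i - 1] * inv2;
            double A[3][3];
            for (int a = 0; a < 3; ++a)
                for (int b = 0; b < 3; ++b)
                    A[a][b] = c * ((a == b ? (l2 - dR2) : 0.0) +
                                   2.0 * d[a] * d[b]);
            for (int a = 0; a < 3; ++a)
                for (int b = 0; b < 3; ++b) {
                    add(i, a, i, b, -A[a][b]);
                    add(i - 1, a, i - 1, b, -A[a][b]);
                    add(i, a, i - 1, b, A[a][b]);
                    add(i - 1, a, i, b, A[a][b]);
                }
        }
        for (int j = 1; j < nn - 1; ++j) { // transverse midpoint penalties
            const double k = kperp[j - 1];
            if (k == 0.0) continue;
            const int nodes[3] = { j, j - 1, j + 1 };
            const double coef[3] = { 1.0, -0.5, -0.5 };
            for (int a = 0; a < 3; ++a)
                for (int b = 0; b < 3; ++b) {
                    const double val = -k * coef[a] * coef[b];
                    for (int cc = 0; cc < 3; ++cc)
                        add(nodes[a], cc, nodes[b], cc, val);
                }
        }
        // banded LU with back substitution (no pivoting; system is
        // I + SPD contribution, strictly diagonally dominant enough)
        std::vector<double> ab(amat);
        std::vector<double> rhs(g);
        for (int i = 0; i < m; ++i) rhs[i] = -g[i];
        // forward elimination
        for (int jcol = 0; jcol < m; ++jcol) {
            const double piv = ab[kb + (size_t)ld * jcol];
            if (!(std::fabs(piv) > 1e-300)) return false;
            const int imax = std::min(m - 1, jcol + kb);
            for (int i = jcol + 1; i <= imax; ++i) {
                const double l = ab[(i - jcol + kb) + (size_t)ld * jcol] / piv;
                if (l == 0.0) continue;
                const int jmax = std::min(m - 1, jcol + kb);
                for (int jj = jcol + 1; jj <= jmax; ++jj)
                    ab[(i - jj + kb) + (size_t)ld * jj] -=
                        l * ab[(jcol - jj + kb) + (size_t)ld * jj];
                rhs[i] -= l * rhs[jcol];
            }
        }
        for (int i = m - 1; i >= 0; --i) {
            double s = rhs[i];
            const int jmax = std::min(m - 1, i + kb);
            for (int jj = i + 1; jj <= jmax; ++jj)
                s -= ab[(i - jj + kb) + (size_t)ld * jj] * rhs[jj];
            rhs[i] = s / ab[kb + (size_t)ld * i];
        }
        double dmax = 0.0;
        for (int j = 0; j < nfree; ++j) {
            x[j + 2] += rhs[3 * j];
            y[j + 2] += rhs[3 * j + 1];
            z[j + 2] += rhs[3 * j + 2];
            dmax = std::max(dmax, std::fabs(rhs[3 * j]));
            dmax = std::max(dmax, std::fabs(rhs[3 * j + 1]));
            dmax = std::max(dmax, std::fabs(rhs[3 * j + 2]));
        }
        if (!std::isfinite(dmax)) return false;
        if (dmax < 1e-12 * dR) return true;
    }
    return false;
}

// Relax one chain over dt (backward Euler; bisects the interval if Newton
// fails). Reflects free nodes at the ground plane afterwards.
static void relax_chain_core(double* x, double* y, double* z, int nseg,
                             double dR, const double* kpar,
                             const double* kperp, double dt, double gamma_s,
                             int depth)
{
    const int nn = nseg + 1;
    std::vector<double> sx(x, x + nn), sy(y, y + nn), sz(z, z + nn);
    if (!implicit_relax_step(x, y, z, nseg, dR, kpar, kperp, dt, gamma_s)) {
        if (depth >= 10)
            stop("chain relaxation failed to converge: reduce dt or increase gamma_s");
        std::copy(sx.begin(), sx.end(), x);
        std::copy(sy.begin(), sy.end(), y);
        std::copy(sz.begin(), sz.end(), z);
        relax_chain_core(x, y, z, nseg, dR, kpar, kperp, dt / 2, gamma_s,
                         depth + 1);
        relax_chain_core(x, y, z, nseg, dR, kpar, kperp, dt / 2, gamma_s,
                         depth + 1);
        return;
    }
    for (int j = 2; j < nn; ++j)
        if (z[j] < 0.0) z[j] = -z[j]; // setae cannot penetrate the ground
}

// [[Rcpp::export]]
NumericVector cpp_longitudinal_force(NumericVector node_j, NumericVector node_k,
                                     double dR, double k_par)
{
    const double dx = node_j[0] - node_k[0];
    const double dy = node_j[1] - node_k[1];
    const double dz = node_j[2] - node_k[2];
    const double l2 = dx * dx + dy * dy + dz * dz;
    if (l2 < COINCIDENT_TOL2)
        stop("coincident nodes: longitudinal force direction undefined");
    const double c = -k_par / (2.0 * dR * dR) * (l2 - dR * dR);
    return NumericVector::create(c * dx, c * dy, c * dz);
}

// [[Rcpp::export]]
NumericVector cpp_transverse_force(NumericVector prev, NumericVector node,
                                   NumericVector nxt, double k_perp)
{
    NumericVector f(3);
    for (int i = 0; i < 3; ++i)
        f[i] = k_perp * (0.5 * (prev[i] + nxt[i]) - node[i]);
    return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_chain_elastic_forces(NumericMatrix nodes, double dR,
                                       NumericVector k_par, NumericVector k_perp)
{
    const int nn = nodes.nrow();
    const int nseg = nn - 1;
    std::vector<double> x(nn), y(nn), z(nn), fx(nn), fy(nn), fz(nn);
    for (int i = 0; i < nn; ++i) {
        x[i] = nodes(i, 0); y[i] = nodes(i, 1); z[i] = nodes(i, 2);
    }
    chain_forces(x.data(), y.data(), z.data(), nseg, dR,
                 REAL(k_par), REAL(k_perp), fx.data(), fy.data(), fz.data());
    NumericMatrix out(nn, 3);
    for (int i = 0; i < nn; ++i) {
        out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_flow_coupling_force(NumericVector p_pos, NumericVector p_vel,
                                      NumericMatrix seg_pos, NumericMatrix seg_vel,
                                      double gamma_seta, double r_f, double r_cut)
{
    const int n = seg_pos.nrow();
    double fx = 0.0, fy = 0.0, fz = 0.0;
    const double rcut2 = r_cut > 0 ? r_cut * r_cut : -1.0;
    for (int j = 0; j < n; ++j) {
        const double dx = p_pos[0] - seg_pos(j, 0);
        const double dy = p_pos[1] - seg_pos(j, 1);
        const double dz = p_pos[2] - seg_pos(j, 2);
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (rcut2 > 0 && r2 > rcut2) continue;
        const double w = gamma_seta * std::exp(-std::sqrt(r2) / r_f);
        fx += w * (seg_vel(j, 0) - p_vel[0]);
        fy += w * (seg_vel(j, 1) - p_vel[1]);
        fz += w * (seg_vel(j, 2) - p_vel[2]);
    }
    return NumericVector::create(fx, fy, fz);
}

// [[Rcpp::export]]
NumericVector cpp_morse_force(NumericVector p_pos, NumericVector node_pos,
                              double u0, double a, double r_vdw)
{
    const double dx = p_pos[0] - node_pos[0];
    const double dy = p_pos[1] - node_pos[1];
    const double dz = p_pos[2] - node_pos[2];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < COINCIDENT_TOL2)
        stop("coincident particle and node: Morse force direction undefined");
    const double r = std::sqrt(r2);
    const double e = std::exp(-a * (r - r_vdw));
    const double fmag = -2.0 * u0 * a * (1.0 - e) * e; // <0 attractive (r > r_vdw)
    return NumericVector::create(fmag * dx / r, fmag * dy / r, fmag * dz / r);
}

// Overdamped relaxation of the free nodes (index >= 2, 0-based) holding the
// base (node 0) and driven node (node 1) fixed (backward Euler over dt);
// velocities are finite differences against prev_nodes over dt.
// [[Rcpp::export]]
List cpp_relax_chain(NumericMatrix nodes, NumericMatrix prev_nodes, double dR,
                     NumericVector k_par, NumericVector k_perp,
                     double dt, double gamma_s)
{
    const int nn = nodes.nrow();
    const int nseg = nn - 1;
    std::vector<double> x(nn), y(nn), z(nn);
    for (int i = 0; i < nn; ++i) {
        x[i] = nodes(i, 0); y[i] = nodes(i, 1); z[i] = nodes(i, 2);
    }
    std::vector<double> x0(x), y0(y), z0(z);
    relax_chain_core(x.data(), y.data(), z.data(), nseg, dR,
                     REAL(k_par), REAL(k_perp), dt, gamma_s, 0);
    double max_disp = 0.0;
    for (int j = 2; j < nn; ++j) {
        const double d2 = (x[j] - x0[j]) * (x[j] - x0[j]) +
                          (y[j] - y0[j]) * (y[j] - y0[j]) +
                          (z[j] - z0[j]) * (z[j] - z0[j]);
        if (d2 > max_disp) max_disp = d2;
        if (!std::isfinite(d2))
            stop("chain relaxation diverged: reduce dt or increase gamma_s");
    }
    max_disp = std::sqrt(max_disp);
    if (max_disp > dR)
        stop("chain relaxation unstable (node moved %.3g > dR per step): reduce dt or increase gamma_s",
             max_disp);
    NumericMatrix out(nn, 3), vel(nn, 3);
    for (int i = 0; i < nn; ++i) {
        out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
        vel(i, 0) = (x[i] - prev_nodes(i, 0)) / dt;
        vel(i, 1) = (y[i] - prev_nodes(i, 1)) / dt;
        vel(i, 2) = (z[i] - prev_nodes(i, 2)) / dt;
    }
    return List::create(_["nodes"] = out, _["velocities"] = vel,
                        _["max_disp"] = max_disp);
}

// Full coupled stepper. Chain node data are passed flattened (all chains
// concatenated); the particle reinjection draws use R's RNG in strict
// particle-index order so event logs are bit-reproducible per seed.
// [[Rcpp::export]]
List cpp_run(List chains, List world, List runp,
             NumericMatrix p_pos, NumericMatrix p_vel,
             NumericMatrix density, int n_eaten0, double t0)
{
    // --- unpack chains ---
    IntegerVector offset = chains["offset"];   // 0-based first node of chain
    IntegerVector nsegv = chains["n_segments"];
    NumericVector base_x = chains["base_x"], base_y = chains["base_y"];
    NumericVector side = chains["side"];
    NumericVector kpar_all = chains["k_par"], kperp_all = chains["k_perp"];
    IntegerVector seg_off = chains["seg_offset"]; // 0-based first segment
    IntegerVector adh_idx = chains["adh_node"];   // 0-based global node index
    NumericVector adh_u0 = chains["adh_u0"];
    NumericVector omega = chains["omega"], phase = chains["phase"];
    NumericVector phi_min = chains["phi_min"], phi_max = chains["phi_max"];
    NumericVector asym = chains["stroke_asym"];
    NumericMatrix nodes0 = chains["nodes"];
    const int nc = offset.size();
    const int nn_all = nodes0.nrow();

    // --- unpack world ---
    const double Lx = world["L_x"], Ly = world["L_y"], Lz = world["L_z"];
    NumericVector mlo = world["mouth_lo"], mhi = world["mouth_hi"];
    NumericVector vext = world["v_ext"];
    const double gamma_seta = world["gamma_seta"], gamma_ext = world["gamma_ext"];
    const double rf = world["r_f"], rcut = world["r_cut"];
    const double mass = world["particle_mass"], gamma_s = world["gamma_s"];
    const double dR = world["dR"];
    const double ma = world["morse_a"], mrv = world["morse_r_vdw"];
    const bool periodic_x = world["periodic_x"];
    const double inj_w = world["injection_frac"];

    // --- unpack run parameters ---
    const int n_steps = runp["n_steps"];
    const double dt = runp["dt"];
    const double t_burn = runp["t_burn"];
    const int series_every = runp["series_every"];
    const bool rec_density = runp["record_density"];

    const int np = p_pos.nrow();
    const int ny = density.nrow(), nz = density.ncol();

    std::vector<double> nx(nn_all), nyv(nn_all), nzv(nn_all);
    std::vector<double> vx(nn_all, 0.0), vy(nn_all, 0.0), vz(nn_all, 0.0);
    for (int i = 0; i < nn_all; ++i) {
        nx[i] = nodes0(i, 0); nyv[i] = nodes0(i, 1); nzv[i] = nodes0(i, 2);
    }
    NumericMatrix nvel0 = chains["node_vel"];
    for (int i = 0; i < nn_all; ++i) {
        vx[i] = nvel0(i, 0); vy[i] = nvel0(i, 1); vz[i] = nvel0(i, 2);
    }
    std::vector<double> px(np), py(np), pz(np), pvx(np), pvy(np), pvz(np);
    for (int p = 0; p < np; ++p) {
        px[p] = p_pos(p, 0); py[p] = p_pos(p, 1); pz[p] = p_pos(p, 2);
        pvx[p] = p_vel(p, 0); pvy[p] = p_vel(p, 1); pvz[p] = p_vel(p, 2);
    }

    std::vector<double> prevx(nn_all), prevy(nn_all), prevz(nn_all);
    std::vector<double> bb(nc * 6);
    const int n_adh = adh_idx.size();
    const double rcut2 = rcut * rcut;
    const double adh_cut = mrv + 16.0 / ma;
    const double adh_cut2 = adh_cut * adh_cut;

    std::vector<double> ev_t;
    std::vector<int> ev_p;
    std::vector<double> ser_t;
    std::vector<int> ser_n;
    int n_eaten = n_eaten0;
    double* dens = REAL(density);

    for (int step = 1; step <= n_steps; ++step) {
        const double t_new = t0 + step * dt;

        // 1) drive + relax each chain, record finite-difference velocities
        for (int c = 0; c < nc; ++c) {
            const int o = offset[c];
            const int nseg = nsegv[c];
            const int nn = nseg + 1;
            for (int i = 0; i < nn; ++i) {
                prevx[o + i] = nx[o + i];
                prevy[o + i] = nyv[o + i];
                prevz[o + i] = nzv[o + i];
            }
            const double mid = 0.5 * (phi_max[c] + phi_min[c]);
            const double amp = 0.5 * (phi_max[c] - phi_min[c]);
            double u = omega[c] * t_new + phase[c] - M_PI_2;
            u -= 2.0 * M_PI * std::floor(u / (2.0 * M_PI));
            const double fd = 1.0 / (1.0 + asym[c]);
            const double w = u < 2.0 * M_PI * fd
                ? u / (2.0 * fd)
                : M_PI + (u - 2.0 * M_PI * fd) / (2.0 * (1.0 - fd));
            const double phi = mid + amp * std::cos(w);
            nx[o + 1] = base_x[c];
            nyv[o + 1] = base_y[c] + dR * side[c] * std::sin(phi);
            nzv[o + 1] = dR * std::cos(phi);
            const double* kpar = REAL(kpar_all) + seg_off[c];
            const double* kperp = REAL(kperp_all) + seg_off[c];
            relax_chain_core(&nx[o], &nyv[o], &nzv[o], nseg, dR, kpar, kperp,
                             dt, gamma_s, 0);
            double bx0 = nx[o], bx1 = nx[o], by0 = nyv[o], by1 = nyv[o],
                   bz0 = nzv[o], bz1 = nzv[o];
            for (int j = 0; j < nn; ++j) {
                const double ddx = nx[o + j] - prevx[o + j];
                const double ddy = nyv[o + j] - prevy[o + j];
                const double ddz = nzv[o + j] - prevz[o + j];
                if (j >= 2 && ddx * ddx + ddy * ddy + ddz * ddz > dR * dR)
                    stop("chain relaxation unstable at t=%.4f: reduce dt or increase gamma_s", t_new);
                vx[o + j] = ddx / dt; vy[o + j] = ddy / dt; vz[o + j] = ddz / dt;
                if (!std::isfinite(nx[o + j] + nyv[o + j] + nzv[o + j]))
                    stop("non-finite chain node at t=%.4f", t_new);
                bx0 = std::min(bx0, nx[o + j]); bx1 = std::max(bx1, nx[o + j]);
                by0 = std::min(by0, nyv[o + j]); by1 = std::max(by1, nyv[o + j]);
                bz0 = std::min(bz0, nzv[o + j]); bz1 = std::max(bz1, nzv[o + j]);
            }
            bb[6 * c] = bx0 - rcut; bb[6 * c + 1] = bx1 + rcut;
            bb[6 * c + 2] = by0 - rcut; bb[6 * c + 3] = by1 + rcut;
            bb[6 * c + 4] = bz0 - rcut; bb[6 * c + 5] = bz1 + rcut;
        }

        // 2) particle step (semi-implicit Euler)
        for (int p = 0; p < np; ++p) {
            double Fx = gamma_ext * (vext[0] - pvx[p]);
            double Fy = gamma_ext * (vext[1] - pvy[p]);
            double Fz = gamma_ext * (vext[2] - pvz[p]);
            const double ppx = px[p], ppy = py[p], ppz = pz[p];
            for (int c = 0; c < nc; ++c) {
                if (ppx < bb[6 * c] || ppx > bb[6 * c + 1] ||
                    ppy < bb[6 * c + 2] || ppy > bb[6 * c + 3] ||
                    ppz < bb[6 * c + 4] || ppz > bb[6 * c + 5]) continue;
                const int o = offset[c];
                const int nn = nsegv[c] + 1;
                for (int j = o; j < o + nn; ++j) {
                    const double dx = ppx - nx[j];
                    const double dy = ppy - nyv[j];
                    const double dz = ppz - nzv[j];
                    const double r2 = dx * dx + dy * dy + dz * dz;
                    if (r2 > rcut2) continue;
                    const double w = gamma_seta * std::exp(-std::sqrt(r2) / rf);
                    Fx += w * (vx[j] - pvx[p]);
                    Fy += w * (vy[j] - pvy[p]);
                    Fz += w * (vz[j] - pvz[p]);
                }
            }
            for (int a = 0; a < n_adh; ++a) {
                const int j = adh_idx[a];
                const double dx = ppx - nx[j];
                const double dy = ppy - nyv[j];
                const double dz = ppz - nzv[j];
                const double r2 = dx * dx + dy * dy + dz * dz;
                if (r2 > adh_cut2 || r2 < COINCIDENT_TOL2) continue;
                const double r = std::sqrt(r2);
                const double e = std::exp(-ma * (r - mrv));
                const double c = -2.0 * adh_u0[a] * ma * (1.0 - e) * e / r;
                Fx += c * dx; Fy += c * dy; Fz += c * dz;
            }
            if (!std::isfinite(Fx + Fy + Fz))
                stop("non-finite force on particle %d at t=%.4f", p + 1, t_new);
            pvx[p] += dt * Fx / mass;
            pvy[p] += dt * Fy / mass;
            pvz[p] += dt * Fz / mass;
            px[p] += dt * pvx[p];
            py[p] += dt * pvy[p];
            pz[p] += dt * pvz[p];
        }

        // 3) boundaries: periodic in x (optional) else reinjection upstream
        for (int p = 0; p < np; ++p) {
            if (periodic_x)
                px[p] -= Lx * std::floor(px[p] / Lx);
            const bool out = px[p] < 0 || px[p] > Lx ||
                             py[p] < -Ly || py[p] > Ly ||
                             pz[p] < 0 || pz[p] > Lz;
            if (out) {
                px[p] = R::runif(0.0, inj_w * Lx);
                py[p] = R::runif(-Ly, Ly);
                pz[p] = R::runif(0.0, Lz);
                pvx[p] = vext[0]; pvy[p] = vext[1]; pvz[p] = vext[2];
            }
        }

        // 4) capture: half-open mouth box, particle-index order
        for (int p = 0; p < np; ++p) {
            if (px[p] >= mlo[0] && px[p] < mhi[0] &&
                py[p] >= mlo[1] && py[p] < mhi[1] &&
                pz[p] >= mlo[2] && pz[p] < mhi[2]) {
                ++n_eaten;
                ev_t.push_back(t_new);
                ev_p.push_back(p + 1);
                px[p] = R::runif(0.0, inj_w * Lx);
                py[p] = R::runif(-Ly, Ly);
                pz[p] = R::runif(0.0, Lz);
                pvx[p] = vext[0]; pvy[p] = vext[1]; pvz[p] = vext[2];
            }
        }

        // 5) density accumulation after burn-in
        if (rec_density && t_new >= t_burn) {
            for (int p = 0; p < np; ++p) {
                int iy = (int)((py[p] + Ly) / (2.0 * Ly) * ny);
                int iz = (int)(pz[p] / Lz * nz);
                iy = std::min(std::max(iy, 0), ny - 1);
                iz = std::min(std::max(iz, 0), nz - 1);
                dens[iy + ny * iz] += 1.0;
            }
        }

        if (series_every > 0 && step % series_every == 0) {
            ser_t.push_back(t_new);
            ser_n.push_back(n_eaten);
        }
    }

    NumericMatrix nodes_out(nn_all, 3), nvel_out(nn_all, 3);
    for (int i = 0; i < nn_all; ++i) {
        nodes_out(i, 0) = nx[i]; nodes_out(i, 1) = nyv[i]; nodes_out(i, 2) = nzv[i];
        nvel_out(i, 0) = vx[i]; nvel_out(i, 1) = vy[i]; nvel_out(i, 2) = vz[i];
    }
    NumericMatrix ppos_out(np, 3), pvel_out(np, 3);
    for (int p = 0; p < np; ++p) {
        ppos_out(p, 0) = px[p]; ppos_out(p, 1) = py[p]; ppos_out(p, 2) = pz[p];
        pvel_out(p, 0) = pvx[p]; pvel_out(p, 1) = pvy[p]; pvel_out(p, 2) = pvz[p];
    }
    return List::create(
        _["nodes"] = nodes_out, _["node_vel"] = nvel_out,
        _["p_pos"] = ppos_out, _["p_vel"] = pvel_out,
        _["n_eaten"] = n_eaten,
        _["event_t"] = NumericVector(ev_t.begin(), ev_t.end()),
        _["event_p"] = IntegerVector(ev_p.begin(), ev_p.end()),
        _["series_t"] = NumericVector(ser_t.begin(), ser_t.end()),
        _["series_n"] = IntegerVector(ser_n.begin(), ser_n.end()),
        _["density"] = density,
        _["t_final"] = t0 + n_steps * dt);
}
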