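descriptor,rho
rho_DIST,0.9795
En_DIST,0.9795
Es_DIST,0.7109
rho_DLAP,0.9544
En_DLAP,0.9467
rho_DSLAP,0.9778
En_DSLAP,0.9389
Es_DSLAP,0.6106
rho_SCHULTZ,0.9797
En_SCHULTZ,0.9809
Es_SCHULTZ,0.7106
rho_HARARY,0.9647
En_HARARY,0.9963
Es_HARARY,0.8340
rho_DEGDIST,0.9521
En_DEGDIST,0.9929
Es_DEGDIST,0.7081
rho_GUTMAN,0.9395
En_GUTMAN,0.9876
Es_GUTMAN,0.7080
rho_SZEGED,0.9143
En_SZEGED,0.9297
rho_PI,0.9557
En_PI,0.9692
Es_PI,0.7080
rho_ABC2,0.6462
En_ABC2,0.9703
Es_ABC2,0.9941
rho_GA2,0.7447
En_GA2,0.9924
Es_GA2,0.9916
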