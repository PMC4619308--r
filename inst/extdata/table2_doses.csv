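cohort,subject,cycle,dose,no_idt,dlt,sex,age,diagnosis,donor,gvhd_acute,gvhd_chronic
1,1,1,5,1,1,F,19,RAEB-2,MSD,0,0
1,1,2,1.5,0,0,F,19,RAEB-2,MSD,0,0
1,1,3,1.5,0,0,F,19,RAEB-2,MSD,0,0
1,1,4,1.5,0,0,F,19,RAEB-2,MSD,0,0
1,2,1,5,1,0,M,36,AML,MSD,0,0
1,2,2,6,0,0,M,36,AML,MSD,0,0
1,2,3,5.5,0,0,M,36,AML,MSD,0,0
1,2,4,6,0,0,M,36,AML,MSD,0,0
1,3,1,5,0,0,M,60,RAEB-2,MUD,1,0
1,3,2,,0,0,M,60,RAEB-2,MUD,1,0
1,3,3,,0,0,M,60,RAEB-2,MUD,1,0
1,3,4,,0,0,M,60,RAEB-2,MUD,1,0
1,4,1,5,1,1,M,48,AML,MSD,0,0
1,4,2,1.5,0,0,M,48,AML,MSD,0,0
1,4,3,2.5,0,0,M,48,AML,MSD,0,0
1,4,4,3,0,0,M,48,AML,MSD,0,0
2,5,1,4,1,0,M,64,RAEB-2,PMUD,1,0
2,5,2,4,0,0,M,64,RAEB-2,PMUD,1,0
2,5,3,5.5,0,0,M,64,RAEB-2,PMUD,1,0
2,5,4,7,0,0,M,64,RAEB-2,PMUD,1,0
2,6,1,4,1,0,F,43,RAEB-2,MSD,0,0
2,6,2,7,0,0,F,43,RAEB-2,MSD,0,0
2,6,3,8,0,0,F,43,RAEB-2,MSD,0,0
2,6,4,12,0,0,F,43,RAEB-2,MSD,0,0
2,7,1,4,1,0,M,64,AML,MSD,0,0
2,7,2,6,0,0,M,64,AML,MSD,0,0
2,7,3,5.5,0,0,M,64,AML,MSD,0,0
2,7,4,5.5,0,0,M,64,AML,MSD,0,0
3,8,1,5,1,0,F,51,RAEB-2,MUD,1,0
3,8,2,7.5,1,1,F,51,RAEB-2,MUD,1,0
3,8,3,7.5,0,1,F,51,RAEB-2,MUD,1,0
3,8,4,7,0,0,F,51,RAEB-2,MUD,1,0
3,9,1,5,1,1,F,59,RAEB-1,MUD,2,0
3,9,2,3.5,0,0,F,59,RAEB-1,MUD,2,0
3,9,3,4,0,0,F,59,RAEB-1,MUD,2,0
3,9,4,4.5,0,0,F,59,RAEB-1,MUD,2,0
3,10,1,5,1,0,F,36,RAEB-2,MUD,1,0
3,10,2,6,1,0,F,36,RAEB-2,MUD,1,0
3,10,3,8.5,0,0,F,36,RAEB-2,MUD,1,0
3,10,4,9,0,0,F,36,RAEB-2,MUD,1,0
4,11,1,5.5,1,0,M,64,RAEB-2,MSD,2,0
4,11,2,2,1,0,M,64,RAEB-2,MSD,2,0
4,11,3,,0,0,M,64,RAEB-2,MSD,2,0
4,11,4,,0,0,M,64,RAEB-2,MSD,2,0
4,12,1,5.5,1,1,M,60,RAEB-2,MSD,0,Mild
4,12,2,4.5,1,0,M,60,RAEB-2,MSD,0,Mild
4,12,3,7,0,0,M,60,RAEB-2,MSD,0,Mild
4,12,4,8,0,0,M,60,RAEB-2,MSD,0,Mild
4,13,1,5.5,1,1,M,41,RAEB-2,MSD,0,0
4,13,2,3,0,0,M,41,RAEB-2,MSD,0,0
4,13,3,5,0,0,M,41,RAEB-2,MSD,0,0
4,13,4,8,0,0,M,41,RAEB-2,MSD,0,0
5,14,1,5,1,0,M,49,AML,MUD,2,0
5,14,2,1.5,0,0,M,49,AML,MUD,2,0
5,14,3,2.5,0,0,M,49,AML,MUD,2,0
5,14,4,3,0,0,M,49,AML,MUD,2,0
5,15,1,5,1,1,F,50,AML,MSD,2,0
5,15,2,4,0,0,F,50,AML,MSD,2,0
5,15,3,6,0,0,F,50,AML,MSD,2,0
5,15,4,9,0,0,F,50,AML,MSD,2,0
5,16,1,5,1,0,F,49,RAEB-2,MSD,2,0
5,16,2,7.5,0,0,F,49,RAEB-2,MSD,2,0
5,16,3,8,0,0,F,49,RAEB-2,MSD,2,0
5,16,4,11,0,1,F,49,RAEB-2,MSD,2,0
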